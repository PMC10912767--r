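# The 17 published PlexusNet configurations (one per detection model).
# block "+" variants use layer normalization instead of batch normalization.
# transformer: [n_blocks, n_heads]; [0, 0] disables transformer blocks.
models:
  - {label: pca,            finding: pca,          block_type: inception,      depth: 7, width: 2, n_junctions: 3, n_short_paths: 1, c1: 32, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 96,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp3_model1,     finding: gp3,          block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 32, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 60,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp3_model2,     finding: gp3,          block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 32, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 60,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp4_model1,     finding: gp4,          block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: avg, fc_channels: 60,  output: sigmoid, n_classes: 1, transformer: [0, 0]}
  - {label: gp4_model2,     finding: gp4,          block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: avg, fc_channels: 60,  output: sigmoid, n_classes: 1, transformer: [0, 0]}
  - {label: gp4_model3,     finding: gp4,          block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 32, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: avg, fc_channels: 60,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp4_model4,     finding: gp4,          block_type: soft_attention, depth: 6, width: 2, n_junctions: 3, n_short_paths: 1, c1: 8,  k1: 3, crop_center: true,  initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 20,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp4_model5,     finding: gp4,          block_type: soft_attention, depth: 6, width: 2, n_junctions: 3, n_short_paths: 1, c1: 8,  k1: 3, crop_center: true,  initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 20,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp4_model6,     finding: gp4,          block_type: residual,       depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 4, normalization: batch, global_pooling: avg, fc_channels: 44,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp5_model1,     finding: gp5,          block_type: soft_attention, depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: avg, fc_channels: 24,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: gp5_model2,     finding: gp5,          block_type: soft_attention, depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: avg, fc_channels: 24,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: ductal,         finding: ductal,       block_type: inception,      depth: 4, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 60,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: cribriform,     finding: cribriform,   block_type: inception,      depth: 3, width: 2, n_junctions: 3, n_short_paths: 1, c1: 32, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: batch, global_pooling: max, fc_channels: 48,  output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: hgpin,          finding: hgpin,        block_type: inception,      depth: 5, width: 4, n_junctions: 2, n_short_paths: 2, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 4, normalization: batch, global_pooling: max, fc_channels: 160, output: softmax, n_classes: 2, transformer: [0, 0]}
  - {label: vessel,         finding: vessel,       block_type: inception,      depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: max, fc_channels: 72,  output: softmax, n_classes: 2, transformer: [3, 4]}
  - {label: nerve,          finding: nerve,        block_type: inception,      depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: max, fc_channels: 72,  output: softmax, n_classes: 2, transformer: [3, 4]}
  - {label: inflammation,   finding: inflammation, block_type: inception,      depth: 5, width: 2, n_junctions: 3, n_short_paths: 1, c1: 16, k1: 5, crop_center: false, initial_filter_factor: 2, normalization: layer, global_pooling: max, fc_channels: 72,  output: softmax, n_classes: 2, transformer: [3, 4]}
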