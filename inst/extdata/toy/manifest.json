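{
  "description": "Hand-enumerated toy fixture: expected values derived by brute-force enumeration of the records above.",
  "n_mutation_records": 11,
  "n_surviving_records": 6,
  "surviving_rows": [1, 2, 3, 4, 5, 6],
  "n_aberrant_cnv_calls_in_panel_retained_samples": 2,
  "samples_with_all_data": ["S1", "S2", "S3"],
  "matrix_shape": [3, 3],
  "n_true_cells": 5,
  "true_cells": [["G1","S1"], ["G2","S1"], ["G1","S2"], ["G2","S2"], ["G3","S3"]]
}
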