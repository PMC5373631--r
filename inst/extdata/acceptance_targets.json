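[
  {"id": "t7", "quantity": "whole-cell major-process branch count",
   "target": 36, "cmp": "eq", "tol": 0},
  {"id": "t8", "quantity": "mean arclength to the three furthest endpoints (um)",
   "target": 39, "cmp": "eq", "tol_rel": 0.02},
  {"id": "t11", "quantity": "minimum cell-body steady concentration, % of maximum",
   "target": 90, "cmp": "ge", "tol": 0},
  {"id": "quarter_volume", "quantity": "quarter-cell volume with FPs (um^3)",
   "target": 530, "cmp": "eq", "tol_rel": 0.02},
  {"id": "quarter_area", "quantity": "quarter-cell area with FPs (um^2)",
   "target": 1683, "cmp": "eq", "tol_rel": 0.02},
  {"id": "body_volume", "quantity": "quarter-cell body volume (um^3)",
   "target": 420, "cmp": "eq", "tol_rel": 0.02},
  {"id": "body_area", "quantity": "quarter-cell body area (um^2)",
   "target": 695, "cmp": "eq", "tol_rel": 0.02},
  {"id": "av_whole", "quantity": "whole-cell A/V (1/um)",
   "target": 3.2, "cmp": "eq", "tol": 0.1},
  {"id": "av_fp", "quantity": "FP A/V (1/um)",
   "target": 9.0, "cmp": "eq", "tol": 0.2},
  {"id": "vfp_share", "quantity": "FP volume share of the cell (%)",
   "target": 20, "cmp": "eq", "tol": 1},
  {"id": "mean_branchpoint", "quantity": "mean centroid-to-branch-point distance (um)",
   "target": 18, "cmp": "eq", "tol_rel": 0.02}
]
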