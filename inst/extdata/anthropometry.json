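{
  "comment": "Bone lengths as fractions of stature; classical segment-proportion values. Pinned by tests; edit only together with them.",
  "stature_fraction": 0.961,
  "ankle_height_fraction": 0.039,
  "vertical_chain": ["LKnee-LAnkle", "LHip-LKnee", "Pelvis-Chest", "Chest-Neck", "Neck-Head", "Head-HeadTop"],
  "fractions": {
    "Pelvis-Chest": 0.188,
    "Chest-Neck": 0.162,
    "Neck-Head": 0.065,
    "Head-HeadTop": 0.055,
    "Neck-LShoulder": 0.129,
    "Neck-RShoulder": 0.129,
    "LShoulder-LElbow": 0.186,
    "RShoulder-RElbow": 0.186,
    "LElbow-LWrist": 0.146,
    "RElbow-RWrist": 0.146,
    "Pelvis-LHip": 0.096,
    "Pelvis-RHip": 0.096,
    "LHip-LKnee": 0.245,
    "RHip-RKnee": 0.245,
    "LKnee-LAnkle": 0.246,
    "RKnee-RAnkle": 0.246,
    "LAnkle-LHeel": 0.049,
    "RAnkle-RHeel": 0.049,
    "LAnkle-LToe": 0.110,
    "RAnkle-RToe": 0.110
  }
}
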