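# msstgcn skeleton layout, schema version 1. 0-based indices.
# 18-keypoint OpenPose COCO body model; template is a frontal standing pose
# in normalized body coordinates (z = 0: 2-D source data).
version: 1
name: coco18
joints:
  - nose
  - neck
  - r_shoulder
  - r_elbow
  - r_wrist
  - l_shoulder
  - l_elbow
  - l_wrist
  - r_hip
  - r_knee
  - r_ankle
  - l_hip
  - l_knee
  - l_ankle
  - r_eye
  - l_eye
  - r_ear
  - l_ear
edges:
  - [0, 1]
  - [1, 2]
  - [2, 3]
  - [3, 4]
  - [1, 5]
  - [5, 6]
  - [6, 7]
  - [1, 8]
  - [8, 9]
  - [9, 10]
  - [1, 11]
  - [11, 12]
  - [12, 13]
  - [0, 14]
  - [14, 16]
  - [0, 15]
  - [15, 17]
template_pose:
  - [0.00, 0.85, 0.00]
  - [0.00, 0.70, 0.00]
  - [-0.22, 0.68, 0.00]
  - [-0.50, 0.66, 0.00]
  - [-0.78, 0.64, 0.00]
  - [0.22, 0.68, 0.00]
  - [0.50, 0.66, 0.00]
  - [0.78, 0.64, 0.00]
  - [-0.12, 0.00, 0.00]
  - [-0.14, -0.45, 0.00]
  - [-0.15, -0.90, 0.00]
  - [0.12, 0.00, 0.00]
  - [0.14, -0.45, 0.00]
  - [0.15, -0.90, 0.00]
  - [-0.05, 0.90, 0.00]
  - [0.05, 0.90, 0.00]
  - [-0.12, 0.87, 0.00]
  - [0.12, 0.87, 0.00]
center_joint: 1
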