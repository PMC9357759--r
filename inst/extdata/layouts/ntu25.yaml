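# msstgcn skeleton layout, schema version 1. 0-based indices.
# 25-joint Kinect-v2 body model (NTU RGB+D convention); 3-D template pose
# in normalized body coordinates.
version: 1
name: ntu25
joints:
  - base_spine
  - mid_spine
  - neck
  - head
  - l_shoulder
  - l_elbow
  - l_wrist
  - l_hand
  - r_shoulder
  - r_elbow
  - r_wrist
  - r_hand
  - l_hip
  - l_knee
  - l_ankle
  - l_foot
  - r_hip
  - r_knee
  - r_ankle
  - r_foot
  - spine
  - l_handtip
  - l_thumb
  - r_handtip
  - r_thumb
edges:
  - [0, 1]
  - [1, 20]
  - [2, 20]
  - [3, 2]
  - [4, 20]
  - [5, 4]
  - [6, 5]
  - [7, 6]
  - [8, 20]
  - [9, 8]
  - [10, 9]
  - [11, 10]
  - [12, 0]
  - [13, 12]
  - [14, 13]
  - [15, 14]
  - [16, 0]
  - [17, 16]
  - [18, 17]
  - [19, 18]
  - [21, 22]
  - [22, 7]
  - [23, 24]
  - [24, 11]
template_pose:
  - [0.00, 0.00, 0.00]
  - [0.00, 0.25, 0.00]
  - [0.00, 0.65, 0.00]
  - [0.00, 0.80, 0.00]
  - [0.20, 0.55, 0.00]
  - [0.45, 0.55, 0.00]
  - [0.70, 0.55, 0.00]
  - [0.80, 0.55, 0.00]
  - [-0.20, 0.55, 0.00]
  - [-0.45, 0.55, 0.00]
  - [-0.70, 0.55, 0.00]
  - [-0.80, 0.55, 0.00]
  - [0.10, -0.05, 0.00]
  - [0.12, -0.45, 0.00]
  - [0.13, -0.85, 0.00]
  - [0.18, -0.92, 0.10]
  - [-0.10, -0.05, 0.00]
  - [-0.12, -0.45, 0.00]
  - [-0.13, -0.85, 0.00]
  - [-0.18, -0.92, 0.10]
  - [0.00, 0.50, 0.00]
  - [0.92, 0.55, 0.00]
  - [0.84, 0.48, 0.05]
  - [-0.92, 0.55, 0.00]
  - [-0.84, 0.48, 0.05]
center_joint: 20
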