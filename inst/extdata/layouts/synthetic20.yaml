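# msstgcn skeleton layout, schema version 1.
# Joint indices in `edges` and `center_joint` are 0-based.
# template_pose is a canonical standing T-pose in normalized body lengths
# (x: left+, y: up+, z: forward+), used to compute the centroid-distance
# neighborhood partition.
version: 1
name: synthetic20
joints:
  - pelvis
  - spine
  - chest
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
edges:
  - [0, 1]
  - [1, 2]
  - [2, 3]
  - [3, 4]
  - [2, 5]
  - [5, 6]
  - [6, 7]
  - [7, 8]
  - [2, 9]
  - [9, 10]
  - [10, 11]
  - [11, 12]
  - [0, 13]
  - [13, 14]
  - [14, 15]
  - [15, 16]
  - [0, 17]
  - [17, 18]
  - [18, 19]
template_pose:
  - [0.00, 0.00, 0.00]
  - [0.00, 0.25, 0.00]
  - [0.00, 0.50, 0.00]
  - [0.00, 0.70, 0.00]
  - [0.00, 0.90, 0.00]
  - [0.22, 0.62, 0.00]
  - [0.50, 0.62, 0.00]
  - [0.78, 0.62, 0.00]
  - [0.90, 0.62, 0.00]
  - [-0.22, 0.62, 0.00]
  - [-0.50, 0.62, 0.00]
  - [-0.78, 0.62, 0.00]
  - [-0.90, 0.62, 0.00]
  - [0.12, -0.08, 0.00]
  - [0.14, -0.50, 0.00]
  - [0.15, -0.92, 0.00]
  - [0.20, -1.00, 0.12]
  - [-0.12, -0.08, 0.00]
  - [-0.14, -0.50, 0.00]
  - [-0.15, -0.92, 0.00]
center_joint: 0
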