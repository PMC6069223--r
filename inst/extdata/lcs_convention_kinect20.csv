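lcs_id,name,origin_a,origin_b,y_from,y_to,w_from,w_to
1,pelvis,hip_center,,hip_center,spine,hip_l,hip_r
2,thorax,spine,,spine,shoulder_center,shoulder_l,shoulder_r
3,head,head,,shoulder_center,head,shoulder_l,shoulder_r
4,shoulder_l,shoulder_l,,elbow_l,shoulder_l,spine,shoulder_center
5,shoulder_r,shoulder_r,,elbow_r,shoulder_r,spine,shoulder_center
6,hip_l,hip_l,,knee_l,hip_l,hip_l,hip_r
7,hip_r,hip_r,,knee_r,hip_r,hip_l,hip_r
8,knee_l,knee_l,,ankle_l,knee_l,hip_l,hip_r
9,knee_r,knee_r,,ankle_r,knee_r,hip_l,hip_r
10,ankle_l,ankle_l,,ankle_l,knee_l,hip_l,hip_r
11,ankle_r,ankle_r,,ankle_r,knee_r,hip_l,hip_r
12,hand_l,hand_l,,hand_l,wrist_l,spine,shoulder_center
13,hand_r,hand_r,,hand_r,wrist_r,spine,shoulder_center
14,girdle_l,shoulder_center,shoulder_l,spine,shoulder_center,shoulder_l,shoulder_r
15,girdle_r,shoulder_center,shoulder_r,spine,shoulder_center,shoulder_l,shoulder_r
16,elbow_l,elbow_l,,wrist_l,elbow_l,spine,shoulder_center
17,elbow_r,elbow_r,,wrist_r,elbow_r,spine,shoulder_center
18,wrist_l,wrist_l,,hand_l,wrist_l,spine,shoulder_center
19,wrist_r,wrist_r,,hand_r,wrist_r,spine,shoulder_center
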