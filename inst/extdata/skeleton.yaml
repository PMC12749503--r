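# Planar skeleton proportions for the synthetic motion generator.
# All lengths/heights are fractions of stature (standard anthropometric
# segment ratios); heights are measured from the ground up.
proportions:
  nose_height: 0.930
  eye_height: 0.940
  ear_height: 0.936
  mouth_height: 0.912
  shoulder_height: 0.818
  hip_height: 0.530
  knee_height: 0.285
  ankle_height: 0.039
  shoulder_halfwidth: 0.129
  hip_halfwidth: 0.0955
  upper_arm: 0.186
  forearm: 0.146
  hand: 0.108
  foot_length: 0.152
  arm_hang_angle: 15   # degrees of outward abduction in the static pose
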