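name,proximal,vertex,distal,plane
left_elbow,11,13,15,sagittal
right_elbow,12,14,16,sagittal
left_shoulder,23,11,13,sagittal
right_shoulder,24,12,14,sagittal
left_hip_sagittal,11,23,25,sagittal
right_hip_sagittal,12,24,26,sagittal
left_hip_frontal,24,23,25,frontal
right_hip_frontal,23,24,26,frontal
left_knee,23,25,27,sagittal
right_knee,24,26,28,sagittal
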