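dataset,method,subject_id,accuracy
iv2a,SE-CNN,1,83.26
iv2a,SE-CNN,2,53.54
iv2a,SE-CNN,3,92.57
iv2a,SE-CNN,4,70.42
iv2a,SE-CNN,5,68.13
iv2a,SE-CNN,6,60.90
iv2a,SE-CNN,7,89.51
iv2a,SE-CNN,8,83.40
iv2a,SE-CNN,9,85.63
iv2a,SSSTN,1,86.46
iv2a,SSSTN,2,58.33
iv2a,SSSTN,3,92.57
iv2a,SSSTN,4,75.35
iv2a,SSSTN,5,80.90
iv2a,SSSTN,6,67.01
iv2a,SSSTN,7,93.06
iv2a,SSSTN,8,85.76
iv2a,SSSTN,9,86.46
iv2b,SE-CNN,1,78.12
iv2b,SE-CNN,2,67.71
iv2b,SE-CNN,3,83.68
iv2b,SE-CNN,4,94.44
iv2b,SE-CNN,5,95.83
iv2b,SE-CNN,6,81.25
iv2b,SE-CNN,7,90.28
iv2b,SE-CNN,8,89.93
iv2b,SE-CNN,9,87.50
iv2b,SSSTN,1,79.58
iv2b,SSSTN,2,70.42
iv2b,SSSTN,3,86.67
iv2b,SSSTN,4,95.42
iv2b,SSSTN,5,95.83
iv2b,SSSTN,6,82.92
iv2b,SSSTN,7,92.08
iv2b,SSSTN,8,90.00
iv2b,SSSTN,9,90.00
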