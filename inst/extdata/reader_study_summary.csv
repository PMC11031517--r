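modality,criterion,reader,mean,sd
PAN,bone_quality,R1,2.35,0.49
PAN,bone_quality,R2,3.53,0.51
PAN,bone_quality,R3,4.06,0.56
PAN,detail_visualization,R1,2.35,0.49
PAN,detail_visualization,R2,3.53,0.51
PAN,detail_visualization,R3,4.00,0.50
PAN,artefacts,R1,2.65,0.49
PAN,artefacts,R2,3.76,0.44
PAN,artefacts,R3,3.35,0.61
PAN,overall_quality,R1,2.29,0.47
PAN,overall_quality,R2,3.53,0.51
PAN,overall_quality,R3,4.00,0.50
PAN,diagnostic_acceptability,R1,2.47,0.51
PAN,diagnostic_acceptability,R2,3.76,0.44
PAN,diagnostic_acceptability,R3,4.00,0.50
PVMI40,bone_quality,R1,2.59,0.51
PVMI40,bone_quality,R2,3.41,0.62
PVMI40,bone_quality,R3,4.35,0.49
PVMI40,detail_visualization,R1,2.47,0.51
PVMI40,detail_visualization,R2,3.35,0.61
PVMI40,detail_visualization,R3,4.29,0.47
PVMI40,artefacts,R1,2.76,0.44
PVMI40,artefacts,R2,3.29,0.59
PVMI40,artefacts,R3,3.35,0.49
PVMI40,overall_quality,R1,2.59,0.51
PVMI40,overall_quality,R2,3.59,0.51
PVMI40,overall_quality,R3,4.12,0.33
PVMI40,diagnostic_acceptability,R1,2.65,0.49
PVMI40,diagnostic_acceptability,R2,3.59,0.51
PVMI40,diagnostic_acceptability,R3,4.18,0.39
PVMI60,bone_quality,R1,2.35,0.49
PVMI60,bone_quality,R2,3.76,0.44
PVMI60,bone_quality,R3,4.18,0.53
PVMI60,detail_visualization,R1,2.29,0.59
PVMI60,detail_visualization,R2,3.47,0.51
PVMI60,detail_visualization,R3,4.18,0.53
PVMI60,artefacts,R1,2.59,0.51
PVMI60,artefacts,R2,3.88,0.33
PVMI60,artefacts,R3,3.65,0.49
PVMI60,overall_quality,R1,2.35,0.49
PVMI60,overall_quality,R2,3.82,0.39
PVMI60,overall_quality,R3,4.12,0.33
PVMI60,diagnostic_acceptability,R1,2.35,0.49
PVMI60,diagnostic_acceptability,R2,3.88,0.33
PVMI60,diagnostic_acceptability,R3,4.24,0.44
PETI_BONE,bone_quality,R1,4.71,0.47
PETI_BONE,bone_quality,R2,5.00,0.00
PETI_BONE,bone_quality,R3,4.88,0.33
PETI_BONE,detail_visualization,R1,3.82,0.64
PETI_BONE,detail_visualization,R2,4.94,0.24
PETI_BONE,detail_visualization,R3,4.47,0.51
PETI_BONE,artefacts,R1,3.88,0.33
PETI_BONE,artefacts,R2,4.82,0.39
PETI_BONE,artefacts,R3,4.00,0.00
PETI_BONE,overall_quality,R1,3.88,0.60
PETI_BONE,overall_quality,R2,5.00,0.00
PETI_BONE,overall_quality,R3,4.71,0.47
PETI_BONE,diagnostic_acceptability,R1,4.06,0.43
PETI_BONE,diagnostic_acceptability,R2,4.94,0.24
PETI_BONE,diagnostic_acceptability,R3,4.53,0.51
PETI_COMBO,bone_quality,R1,4.47,0.62
PETI_COMBO,bone_quality,R2,3.82,0.39
PETI_COMBO,bone_quality,R3,4.76,0.44
PETI_COMBO,detail_visualization,R1,3.71,0.59
PETI_COMBO,detail_visualization,R2,3.59,0.51
PETI_COMBO,detail_visualization,R3,4.35,0.49
PETI_COMBO,artefacts,R1,3.82,0.39
PETI_COMBO,artefacts,R2,3.12,0.49
PETI_COMBO,artefacts,R3,4.06,0.24
PETI_COMBO,overall_quality,R1,3.76,0.56
PETI_COMBO,overall_quality,R2,3.59,0.51
PETI_COMBO,overall_quality,R3,4.76,0.44
PETI_COMBO,diagnostic_acceptability,R1,3.94,0.43
PETI_COMBO,diagnostic_acceptability,R2,3.53,0.51
PETI_COMBO,diagnostic_acceptability,R3,4.35,0.49
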