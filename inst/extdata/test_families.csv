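test_family,code_type,code
chemistry,professional,80048
chemistry,professional,80053
chemistry,professional,80061
chemistry,professional,82947
chemistry,professional,83036
chemistry,professional,83037
chemistry,professional,83721
chemistry,professional,84443
chemistry,professional,85025
chemistry,revenue,0300
chemistry,revenue,0301
chemistry,revenue,0305
xray,professional,71045
xray,professional,71046
xray,professional,73030
xray,professional,73562
xray,revenue,0320
ct,professional,70450
ct,professional,71250
ct,professional,74177
ct,revenue,0350
mri,professional,70551
mri,professional,72148
mri,professional,73721
mri,revenue,0610
ultrasound,professional,76700
ultrasound,professional,76805
ultrasound,professional,93306
ultrasound,revenue,0402
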