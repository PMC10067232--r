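NRRD0004
# hand-written fixture: 4 x 3 x 2 int16 volume, ascii encoding
type: short
dimension: 3
space: left-posterior-superior
sizes: 4 3 2
space directions: (0.8,0,0) (0,0.8,0) (0,0,3)
kinds: domain domain domain
encoding: ascii
space origin: (-1.2,-0.8,0)

-100 -100 -100 -100
-100 1200 1200 -100
-100 -100 -100 -100
-100 1200 1200 -100
-100 1200 1200 -100
-100 -100 -100 -100
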