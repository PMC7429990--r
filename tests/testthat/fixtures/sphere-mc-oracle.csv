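# Synthetic Monte-Carlo reference (random walk, reflecting sphere)
# PGSE delta=1 ms, Delta=30 ms, b=5 ms/um^2, gradient along z
# 30000 walkers, rms step <= 0.1 um (0.05 at r=2 and r=5,D=3), seed 20200415
# generated once by tools/mc_sphere_oracle.py
r_um,D_um2_ms,attenuation_mc,se_mc
2.0,1.0,0.907739,0.000642
2.0,3.0,0.943893,0.000407
5.0,1.0,0.427277,0.003270
5.0,3.0,0.473682,0.003069
10.0,1.0,0.071397,0.004066
10.0,3.0,0.013397,0.004072
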