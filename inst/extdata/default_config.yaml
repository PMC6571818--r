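# Default screening constraints; keys mirror screening_constraints().
tol_ppm: 3
min_intensity: 20000
c_range: [1, 90]
h_range: [1, 190]
o_range: [0, 18]
n_range: [0, 5]
s_range: [0, 1]
hc_min: 0.1
hc_max: 3.5
dbe_min: 0
dbe_max: 40
sn_min: 3
min_peak_area: 1000
mz_min: 100
mz_max: 600
rt_tol_min: 0.2
shape_min: 0.8
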