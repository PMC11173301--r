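# provenance: bindspec synthetic parametric basis v1
# description: Gaussian-band reference MRE curves; helix minima 208/222 nm, sheet minimum 217 nm, coil minimum 198 nm
# units: deg cm^2 dmol^-1
wavelength_nm,helix,sheet,coil
200.0,21853.7,20998.6,-39346.3
200.5,16826.9,19292.3,-38369.2
201.0,11858.7,17492.8,-37214.9
201.5,6986.71,15623.6,-35899.2
202.0,2245.78,13707.6,-34440
202.5,-2331.71,11766.8,-32856.7
203.0,-6716.17,9821.85,-31169.7
203.5,-10881,7891.26,-29400
204.0,-14802.6,5991.57,-27568.9
204.5,-18460.9,4137.04,-25697.4
205.0,-21839,2339.55,-23806
205.5,-24923.8,608.656,-21913.9
206.0,-27706.1,-1048.31,-20039.3
206.5,-30180.6,-2626.09,-18198.7
207.0,-32346.1,-4121.22,-16406.9
207.5,-34205.6,-5531.87,-14676.6
208.0,-35766.1,-6857.49,-13018.9
208.5,-37038.6,-8098.6,-11442.5
209.0,-38037.8,-9256.46,-9954.28
209.5,-38781.9,-10332.9,-8559.27
210.0,-39291.8,-11330,-7260.57
210.5,-39591.1,-12250,-6059.64
211.0,-39704.9,-13095.2,-4956.44
211.5,-39659.7,-13867.5,-3949.6
212.0,-39482.2,-14569,-3036.59
212.5,-39199,-15201.1,-2213.97
213.0,-38835.5,-15765.3,-1477.53
213.5,-38415.5,-16262.6,-822.48
214.0,-37960.9,-16694,-243.647
214.5,-37490.4,-17060.1,264.398
215.0,-37020.2,-17361.6,707.188
215.5,-36562.8,-17599.1,1090.25
216.0,-36127.5,-17773.3,1418.98
216.5,-35720.3,-17884.7,1698.62
217.0,-35343.6,-17934.4,1934.12
217.5,-34997.1,-17923.4,2130.15
218.0,-34677.7,-17853.1,2291.04
218.5,-34379.8,-17725.2,2420.79
219.0,-34096.2,-17541.7,2523.02
219.5,-33818.1,-17304.8,2601.03
220.0,-33535.9,-17017.2,2657.76
220.5,-33239.5,-16681.9,2695.84
221.0,-32918.8,-16302.1,2717.62
221.5,-32564.3,-15881.4,2725.13
222.0,-32167.2,-15423.4,2720.21
222.5,-31719.8,-14932.3,2704.43
223.0,-31215.6,-14412.1,2679.2
223.5,-30649.8,-13867,2645.72
224.0,-30019.2,-13301.3,2605.08
224.5,-29322.3,-12719.3,2558.21
225.0,-28559,-12125.2,2505.95
225.5,-27731,-11523.3,2449.03
226.0,-26841.4,-10917.4,2388.12
226.5,-25894.7,-10311.6,2323.81
227.0,-24896.6,-9709.29,2256.64
227.5,-23853.5,-9114.01,2187.1
228.0,-22772.7,-8528.86,2115.63
228.5,-21662.3,-7956.68,2042.65
229.0,-20530.4,-7400.01,1968.55
229.5,-19385.4,-6861.08,1893.68
230.0,-18235.6,-6341.79,1818.37
230.5,-17089.3,-5843.74,1742.94
231.0,-15954.1,-5368.21,1667.68
231.5,-14837.5,-4916.18,1592.84
232.0,-13746.1,-4488.34,1518.69
232.5,-12685.9,-4085.1,1445.45
233.0,-11662.3,-3706.64,1373.34
233.5,-10679.9,-3352.87,1302.55
234.0,-9742.33,-3023.52,1233.26
234.5,-8852.6,-2718.12,1165.62
235.0,-8012.88,-2436.04,1099.78
235.5,-7224.62,-2176.5,1035.85
236.0,-6488.57,-1938.62,973.941
236.5,-5804.83,-1721.42,914.143
237.0,-5172.93,-1523.84,856.528
237.5,-4591.86,-1344.79,801.15
238.0,-4060.18,-1183.11,748.053
238.5,-3576.08,-1037.67,697.263
239.0,-3137.42,-907.3,648.794
239.5,-2741.85,-790.865,602.647
240.0,-2386.81,-687.248,558.811
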