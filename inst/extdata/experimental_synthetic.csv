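wavelength_nm,delta_epsilon
180.0000,-0.001341
182.0000,-0.003724
184.0000,-0.009511
186.0000,-0.022443
188.0000,-0.049142
190.0000,-0.100269
192.0000,-0.191377
194.0000,-0.342939
196.0000,-0.578945
198.0000,-0.923760
200.0000,-1.397362
202.0000,-2.009723
204.0000,-2.755632
206.0000,-3.611411
208.0000,-4.534761
210.0000,-5.468229
212.0000,-6.345884
214.0000,-7.101960
216.0000,-7.679721
218.0000,-8.038786
220.0000,-8.159646
222.0000,-8.044747
224.0000,-7.716368
226.0000,-7.212062
228.0000,-6.578792
230.0000,-5.866901
232.0000,-5.124859
234.0000,-4.395343
236.0000,-3.712891
238.0000,-3.103010
240.0000,-2.582440
242.0000,-2.160197
244.0000,-1.838990
246.0000,-1.616707
248.0000,-1.487765
250.0000,-1.444198
252.0000,-1.476458
254.0000,-1.573975
256.0000,-1.725528
258.0000,-1.919502
260.0000,-2.144112
262.0000,-2.387611
264.0000,-2.638543
266.0000,-2.886011
268.0000,-3.119975
270.0000,-3.331533
272.0000,-3.513182
274.0000,-3.659017
276.0000,-3.764856
278.0000,-3.828286
280.0000,-3.848612
282.0000,-3.826738
284.0000,-3.764970
286.0000,-3.666777
288.0000,-3.536521
290.0000,-3.379169
292.0000,-3.200026
294.0000,-3.004477
296.0000,-2.797770
298.0000,-2.584835
300.0000,-2.370149
302.0000,-2.157640
304.0000,-1.950635
306.0000,-1.751839
308.0000,-1.563352
310.0000,-1.386696
312.0000,-1.222873
314.0000,-1.072421
316.0000,-0.935488
318.0000,-0.811896
320.0000,-0.701210
322.0000,-0.602802
324.0000,-0.515904
326.0000,-0.439659
328.0000,-0.373164
330.0000,-0.315499
332.0000,-0.265759
334.0000,-0.223071
336.0000,-0.186609
338.0000,-0.155606
340.0000,-0.129356
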