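batch	replicate	Sp_six_peaks	Sp_three_ginsenosides
PG01	1	1.08e5	1.01e5
PG01	2	9.26e4	8.81e4
PG01	3	9.09e4	8.66e4
PG02	1	2.44e5	1.61e5
PG02	2	2.05e5	1.88e5
PG02	3	1.36e5	1.23e5
PG03	1	7.52e4	7.39e4
PG03	2	4.51e4	3.59e4
PG03	3	3.92e4	3.92e4
PG04	1	1.73e5	1.57e5
PG04	2	1.57e5	1.42e5
PG04	3	1.57e5	1.43e5
PG05	1	1.73e5	1.60e5
PG05	2	1.39e5	1.31e5
PG05	3	1.23e5	1.20e5
GG	1	2.54e4	1.84e4
GG	2	2.48e4	2.09e4
GG	3	2.15e4	1.88e4
FG	1	3.64e4	3.33e4
FG	2	3.52e4	3.44e4
FG	3	8.09e4	7.68e4
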