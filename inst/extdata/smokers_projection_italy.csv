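year,male,female
2012,23.44,14.55
2017,22.10,14.24
2022,19.37,12.06
2027,16.96,9.58
2032,14.72,7.05
2037,11.73,6.37
2042,9.09,4.58
2047,6.45,2.80
2052,3.80,1.01
2057,1.16,0.00
2062,0.00,0.00
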