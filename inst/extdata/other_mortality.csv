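ageband,sex,rate
30-34,female,6e-04
30-34,male,0.00075
35-39,female,0.000931624331106802
35-39,male,0.0011645304138835
40-44,female,0.00144653982385033
40-44,male,0.00180817477981291
45-49,female,0.00224605282635652
45-49,male,0.00280756603294565
50-54,female,0.00348746243664155
50-54,male,0.00435932804580194
55-59,female,0.00541500809966047
55-59,male,0.00676876012457559
60-64,female,0.00840792216464016
60-64,male,0.0105099027058002
65-69,female,0.0130550414377182
65-69,male,0.0163188017971478
70-74,female,0.0202706570783097
70-74,male,0.0253383213478872
75-79,female,0.0314743955694594
75-79,male,0.0393429944618243
80-84,female,0.0488705211989808
80-84,male,0.0610881514987261
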