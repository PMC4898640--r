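disease,ageband,sex,rate
chd,30-34,female,0.0002145
chd,30-34,male,0.00039
chd,35-39,female,0.000319996397644053
chd,35-39,male,0.000581811632080095
chd,40-44,female,0.000477378529161634
chd,40-44,male,0.000867960962112062
chd,45-49,female,0.00071216507992699
chd,45-49,male,0.00129484559986725
chd,50-54,female,0.00106242545503275
chd,50-54,male,0.00193168264551409
chd,55-59,female,0.00158495253322062
chd,55-59,male,0.00288173187858295
chd,60-64,female,0.00236447133364762
chd,60-64,male,0.00429903878845022
chd,65-69,female,0.00352737673240032
chd,65-69,male,0.00641341224072785
chd,70-74,female,0.00526222772727996
chd,70-74,male,0.00956768677687265
chd,75-79,female,0.00785032128816893
chd,75-79,male,0.0142733114330344
chd,80-84,female,0.0117113031821094
chd,80-84,male,0.0212932785129263
stroke,30-34,female,0.000144
stroke,30-34,male,0.00018
stroke,35-39,female,0.000225836954710584
stroke,35-39,male,0.00028229619338823
stroke,40-44,female,0.000354182848006601
stroke,40-44,male,0.000442728560008251
stroke,45-49,female,0.000555469276420364
stroke,45-49,male,0.000694336595525455
stroke,50-54,female,0.000871149234875464
stroke,50-54,male,0.00108893654359433
stroke,55-59,female,0.00136623396043563
stroke,55-59,male,0.00170779245054454
stroke,60-64,female,0.00214268136838169
stroke,60-64,male,0.00267835171047711
stroke,65-69,female,0.00336039329965575
stroke,65-69,male,0.00420049162456969
stroke,70-74,female,0.00527014575988963
stroke,70-74,male,0.00658768219986204
stroke,75-79,female,0.00826523381454425
stroke,75-79,male,0.0103315422681803
stroke,80-84,female,0.0129624669072751
stroke,80-84,male,0.0162030836340939
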