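disease,ageband,sex,cf
chd,30-34,female,0.0112965750621676
chd,30-34,male,0.011891131644387
chd,35-39,female,0.0155637333744633
chd,35-39,male,0.0163828772362772
chd,40-44,female,0.0214060074836249
chd,40-44,male,0.0225326394564473
chd,45-49,female,0.0293724043684819
chd,45-49,male,0.0309183203878757
chd,50-54,female,0.0401752832499321
chd,50-54,male,0.0422897718420338
chd,55-59,female,0.0547152170046401
chd,55-59,male,0.0575949652680422
chd,60-64,female,0.074088823372898
chd,60-64,male,0.0779882351293664
chd,65-69,female,0.0995594104421832
chd,65-69,male,0.104799379412824
chd,70-74,female,0.132462179313568
chd,70-74,male,0.13943387296165
chd,75-79,female,0.174013818493099
chd,75-79,male,0.183172440519051
chd,80-84,female,0.225012235059487
chd,80-84,male,0.236854984273145
stroke,30-34,female,0.0187065099543546
stroke,30-34,male,0.0187065099543546
stroke,35-39,female,0.0263393196252834
stroke,35-39,male,0.0263393196252834
stroke,40-44,female,0.036969209296677
stroke,40-44,male,0.036969209296677
stroke,45-49,female,0.0516614354660848
stroke,45-49,male,0.0516614354660848
stroke,50-54,female,0.0717575422637513
stroke,50-54,male,0.0717575422637513
stroke,55-59,female,0.0988560731781694
stroke,55-59,male,0.0988560731781694
stroke,60-64,female,0.134703051952028
stroke,60-64,male,0.134703051952028
stroke,65-69,female,0.180938793152142
stroke,65-69,male,0.180938793152142
stroke,70-74,female,0.23866728515709
stroke,70-74,male,0.23866728515709
stroke,75-79,female,0.307890495698212
stroke,75-79,male,0.307890495698212
stroke,80-84,female,0.386985823860665
stroke,80-84,male,0.386985823860665
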