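tree,category,count
negative.CP,negative.CP.suspect.L,142
negative.CP,negative.CP.suspect.M,234
negative.CP,negative.CP.suspect.H,242
negative.CP,negative.CP.filler.L,180
negative.CP,negative.CP.filler.M,246
negative.CP,negative.CP.filler.H,48
negative.CP,negative.CP.reject.L,213
negative.CP,negative.CP.reject.M,187
negative.CP,negative.CP.reject.H,73
negative.CA,negative.CA.suspect.L,65
negative.CA,negative.CA.suspect.M,97
negative.CA,negative.CA.suspect.H,35
negative.CA,negative.CA.filler.L,253
negative.CA,negative.CA.filler.M,305
negative.CA,negative.CA.filler.H,69
negative.CA,negative.CA.reject.L,287
negative.CA,negative.CA.reject.M,323
negative.CA,negative.CA.reject.H,131
positive.CP,positive.CP.suspect.L,53
positive.CP,positive.CP.suspect.M,195
positive.CP,positive.CP.suspect.H,375
positive.CP,positive.CP.filler.L,92
positive.CP,positive.CP.filler.M,227
positive.CP,positive.CP.filler.H,164
positive.CP,positive.CP.reject.L,95
positive.CP,positive.CP.reject.M,164
positive.CP,positive.CP.reject.H,200
positive.CA,positive.CA.suspect.L,24
positive.CA,positive.CA.suspect.M,87
positive.CA,positive.CA.suspect.H,109
positive.CA,positive.CA.filler.L,109
positive.CA,positive.CA.filler.M,301
positive.CA,positive.CA.filler.H,224
positive.CA,positive.CA.reject.L,128
positive.CA,positive.CA.reject.M,256
positive.CA,positive.CA.reject.H,327
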