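sample,bf_level,sex,non_interoceptive,unclassified,interoceptive
full,3,male,30,24,49
full,3,female,39,28,96
full,10,male,13,49,41
full,10,female,21,62,80
full,30,male,0,76,27
full,30,female,0,94,69
full_matched,3,male,24,22,37
full_matched,3,female,31,21,79
full_matched,10,male,9,45,29
full_matched,10,female,14,52,65
full_matched,30,male,0,65,18
full_matched,30,female,0,74,57
screened,3,male,23,19,32
screened,3,female,20,16,59
screened,10,male,8,39,27
screened,10,female,12,32,51
screened,30,male,0,55,19
screened,30,female,0,51,44
screened_matched,3,male,23,19,32
screened_matched,3,female,16,15,47
screened_matched,10,male,8,39,27
screened_matched,10,female,9,29,40
screened_matched,30,male,0,55,19
screened_matched,30,female,0,44,34
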