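key,value
bnf_pairs,51481
thesaurus_pairs,38037
micromedex_pairs,65446
bnf_thesaurus_shared,14576
bnf_micromedex_shared,14433
thesaurus_micromedex_shared,11574
triple_shared,6970
bnf_severity_1,12644
bnf_severity_2,4997
bnf_severity_3,273
bnf_severity_4,33705
thesaurus_severity_1,2949
thesaurus_severity_2,12779
thesaurus_severity_3,8195
thesaurus_severity_4,14114
micromedex_severity_1,5730
micromedex_severity_2,41713
micromedex_severity_3,15890
micromedex_severity_4,2113
joint_critical_bnf_thesaurus,2429
joint_critical_bnf_micromedex,6026
joint_critical_thesaurus_micromedex,5014
joint_critical_all_three,1768
intersection_critical_bnf,3024
intersection_critical_thesaurus,3647
intersection_critical_micromedex,5681
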