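baseline,followup,count
isolated_ips,isolated_ips,5
isolated_ips,multidomain,11
isolated_memory,isolated_memory,9
isolated_memory,multidomain,5
isolated_memory,preserved,2
isolated_efwm,isolated_ips,1
isolated_efwm,isolated_memory,1
isolated_efwm,isolated_efwm,9
isolated_efwm,multidomain,7
isolated_efwm,preserved,6
isolated_attention,isolated_memory,2
isolated_attention,isolated_efwm,3
isolated_attention,isolated_attention,2
isolated_attention,multidomain,3
isolated_attention,preserved,7
multidomain,isolated_ips,4
multidomain,isolated_memory,4
multidomain,isolated_efwm,3
multidomain,isolated_attention,2
multidomain,multidomain,80
multidomain,preserved,2
preserved,isolated_ips,2
preserved,isolated_memory,10
preserved,isolated_efwm,10
preserved,isolated_attention,8
preserved,multidomain,9
preserved,preserved,33
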