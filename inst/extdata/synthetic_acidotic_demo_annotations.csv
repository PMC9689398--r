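record_id,channel,type,onset_s,offset_s,peak_s
synthetic_acidotic_demo,fhr,variable_deceleration,64.5,106.75,NA
synthetic_acidotic_demo,fhr,variable_deceleration,179.75,227.75,NA
synthetic_acidotic_demo,fhr,acceleration,270,312.5,NA
synthetic_acidotic_demo,uc,contraction,43.75,129.25,86.5
synthetic_acidotic_demo,uc,contraction,216.5,276.5,246.5
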