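variable	group	n_yes	n_total
female	HC	30	56
female	WMH-NC	14	40
female	WMH-CI	24	49
hypertension	HC	12	56
hypertension	WMH-NC	26	40
hypertension	WMH-CI	26	49
diabetes	HC	3	56
diabetes	WMH-NC	7	40
diabetes	WMH-CI	9	49
dyslipidemia	HC	11	56
dyslipidemia	WMH-NC	6	40
dyslipidemia	WMH-CI	6	49
smoking	HC	13	56
smoking	WMH-NC	12	40
smoking	WMH-CI	9	49
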