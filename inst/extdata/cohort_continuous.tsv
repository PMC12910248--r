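variable	group	mean	sd	n
age	HC	61.50	7.52	56
age	WMH-NC	63.75	6.84	40
age	WMH-CI	64.94	7.88	49
education	HC	9.02	4.33	56
education	WMH-NC	7.91	4.73	40
education	WMH-CI	7.94	3.85	49
moca	HC	26.00	2.37	56
moca	WMH-NC	24.35	3.30	40
moca	WMH-CI	17.20	5.20	49
mmse	HC	28.70	1.26	56
mmse	WMH-NC	27.68	2.02	40
mmse	WMH-CI	22.53	5.09	49
avlt	HC	50.11	9.38	56
avlt	WMH-NC	45.55	11.15	40
avlt	WMH-CI	34.85	11.81	47
fds	HC	13.09	3.48	55
fds	WMH-NC	12.41	2.78	39
fds	WMH-CI	10.22	2.99	48
bds	HC	7.20	2.05	55
bds	WMH-NC	6.77	2.71	39
bds	WMH-CI	4.77	1.98	48
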