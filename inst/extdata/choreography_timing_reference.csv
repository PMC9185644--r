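gesture_id,fsr_onset_ms,classifier_onset_ms,fsr_duration_ms,classifier_duration_ms
1,4740,4680,1080,810
8,9600,9540,1200,540
2,15030,15390,1260,450
7,21270,21330,1260,540
5,27210,27270,1470,990
4,33390,33390,960,540
6,39120,39330,1320,630
3,46350,46530,1140,540
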