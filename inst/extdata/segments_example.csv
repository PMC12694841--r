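label,onset_s,duration_s,condition
rest,0,300,
film01,330,120,amusement
film02,480,120,fear
film03,630,120,sad
film04,780,120,disgust
film05,930,120,neutral
film06,1080,120,neutral
film07,1230,120,sad
film08,1380,120,neutral
film09,1530,120,disgust
film10,1680,120,tender
film11,1830,120,disgust
film12,1980,120,fear
film13,2130,120,sad
film14,2280,120,amusement
film15,2430,120,amusement
film16,2580,120,tender
film17,2730,120,tender
film18,2880,120,fear
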