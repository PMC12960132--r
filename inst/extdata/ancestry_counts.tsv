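ancestry	count
Chinese	879
Malay	179
Indian	96
Filipino	13
Nepalese	6
Caucasian	5
Sri Lankan	4
Myanmar	3
Arab	3
Bangladeshi	3
Pakistani	3
Vietnamese	3
Boyanese	3
African	3
Indonesian	3
Javanese	2
Korean	2
Burmese	2
Chinese-thai	1
Unknown	1
Singhalese-chinese	1
Jew-chinese	1
Chinese-burmese	1
Chinese-japanese	1
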