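category C1: 6 pattern positions (5 displayed)
histogram:        ....*..6..8..8..9...........................................
SG1_seq001        DQRKAACCLQDIVFWAFFPCYCWWCEDEPHKPPSRLDRIQQMEWGSCLVVIYGCRCDHNF
SG1_seq002        GCCFAQMCMEDYIIFPFVIYCNQKVTTGNMVWMITASKRYLRGAWVQQGSSEQLYTRLQW
SG1_seq003        EAVVAHKCTLDIWFWCFIMLDMDDYAPVLDDYCWRFCDNQHLERHDEAVGKHTEHYNISI
pattern:          ....A..C..D..F..F...........................................
wt_res_freqs:     ....9..7..9..9..8...........................................
bg|pattern:       ....M..M..D..C..D...........................................
bg|wt_res_freqs:  ....0..0..1..0..0...........................................
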