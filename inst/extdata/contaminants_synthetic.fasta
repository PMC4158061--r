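>CONTAM001_SYNTHETIC keratin-like synthetic contaminant (not a real protein)
MSYNTHETICKERATINLIKEPRGTEINSEQVENCEFGRTESTINGPVRPGSESGNLYAA
KDTTATTSAGSGSGSRGGFGGGYGGGSSRVSSVR
>CONTAM002_SYNTHETIC trypsin-like synthetic contaminant (not a real protein)
MSYNTHETICTRYPTICENZYMESTANDINSEQVENCEIVGGYTCGANTVPYQVSLNSGY
HFCGGSLINSQWVVSAAHCYKSG
>CONTAM003_SYNTHETIC albumin-like synthetic contaminant (not a real protein)
MSYNTHETICALBVMINSTANDINKVPQVSTPTLVEVSRNLGKVGSKCCKHPEAKRMPCA
EDYLSVVLNQLCVLHEKTPVSDRVTKCCTESLVNRRPCFSALEVDETYVPK
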