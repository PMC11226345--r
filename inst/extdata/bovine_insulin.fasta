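>chainA bovine insulin A chain (21 aa)
GIVEQCCASVCSLYQLENYCN
>chainB bovine insulin B chain (30 aa)
FVNQHLCGSHLVEALYLVCGERGFFYTPKA
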