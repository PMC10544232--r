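>synthetic_human_like SYNTHETIC toy gelsolin-like ortholog (not a real protein)
MKTLEDAFRGWQSVHPNTGEKLLAYDVQRGEVRLFEGGVASGFKHVETNDYNVQRLRLDS
AGQPIWEDLGKRTPEMVKALG
>synthetic_zebrafish_like SYNTHETIC toy ortholog with scattered substitutions
MKSLEDAFRGWQAVHPNTGDKLLAYDVQRGEVKLFEGGVSSGFKHVETNEYNVQRLRLDS
SGQPIWEDLGKRSPEMVKALG
>synthetic_mouse_like SYNTHETIC toy ortholog, substitution at the queried arginine
MKTLEDAFRGWQSVHPNTGEKLLAYDVQWGEVRLFEGGVASGFKHVETNDYNVQRLRLDS
AGQPIWEDLGKRTPEMVKALG
>synthetic_frog_like SYNTHETIC toy ortholog with an internal deletion
MKTLEDAFRGWQSVHPNTGEKLLAYDVQRGEVRLFEGGVASGFKHVETNDYNVQRLDS
AGQPIWEDLGKRTPEMVKALG
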