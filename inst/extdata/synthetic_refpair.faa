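>HTkA_syn synthetic stand-in for the HTkA-like reference (67 aa)
MGELPIAPIGRIIKNAGEERVSDEAREAAAKVLAYKGREIASEAVLLALHAGKKTVKAEDIELAVRR
>HTkB_syn synthetic stand-in for the HTkB-like reference (67 aa)
MGELAIAPIGRVIKNAGTERVSDESREATAKVLAKKGREIANEAVFLALHAGRKTVKSEDIELTVRR
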