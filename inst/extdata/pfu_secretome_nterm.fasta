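>PF1109 hypothetical protein / extracellular starch binding protein
MRRNAQVFAMVLLLVLSGIPKALALYTPTPFSID
>PF1209 oligopeptide ABC transporter, oligopeptide-binding protein
MKRLVGVLIGAFVIFGVFGQVVAAQEQELPREET
>PF1399 putative ATPase, vanadate-sensitive
MKVKKIAALAVGAAVAGATLGFASAQGEVPEIPKD
>PF0477 alpha amylase
MNIKKLTPLLTLLLFFIVLASPVSAAKYLELEEGGV
>PF1935 amylopullulanase
MSRKLSLLLVFLIFGSMLGANNIVKAEEPKPLNVII
>PF0190 hypothetical protein, solute-binding
MRKKLVGILTILVALGMLVSPLLKPVAAEDQKVLKIAM
>PF1505 hypothetical protein, translocon-associated
MKKASILLIIMLIASGLTIFNPKALGLEKYSTLT
>PF1938 maltotriose-binding protein
MRRATYAFALLAILVLGVVASGCIGGGTTTPT
>PF1408 putative dipeptide-binding protein
MKKGLLAILLVGVMVLGTFGSGCIGGGTQTQT
>PF0119 periplasmic sugar binding protein
MKHKAVFLLVVLISGVLASGCIGGETKETQ
>PF1774 iron (III) ABC transporter, ATP-binding protein
MKRAIPVFLLIVLVWISGCIGGGTSTIP
>PF1695 hypothetical lipoprotein, basic membrane protein
MRKVGITLSVVALVIMGFVAGCIGGTQTQGE
>PF0337 flagellin
MKKGAIGIGTLIVFIAMVLVAAVAAGVLI
>PF0287 pyrolysin
MNKKGLTVLFIAIMLLSVVPVHFVS
>PF1304 hypothetical protein
MRRGFIINSTLLILIIPLLLLAATYAEI
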