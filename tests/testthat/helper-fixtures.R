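# Reference N-terminal fragments of the experimentally verified
# P. furiosus secretome, built in code so tests do not depend on the
# bundled extdata copies (a separate test checks the two agree).

ref_fragments <- function() {
  tibble::tribble(
    ~id, ~sp_class, ~cleavage_after, ~sequence,
    "PF1109", "SPASE_I", 24L, "MRRNAQVFAMVLLLVLSGIPKALALYTPTPFSID",
    "PF1209", "SPASE_I", 24L, "MKRLVGVLIGAFVIFGVFGQVVAAQEQELPREET",
    "PF1399", "SPASE_I", 25L, "MKVKKIAALAVGAAVAGATLGFASAQGEVPEIPKD",
    "PF0477", "SPASE_I", 26L, "MNIKKLTPLLTLLLFFIVLASPVSAAKYLELEEGGV",
    "PF1935", "SPASE_I", 26L, "MSRKLSLLLVFLIFGSMLGANNIVKAEEPKPLNVII",
    "PF0190", "SPASE_I", 28L, "MRKKLVGILTILVALGMLVSPLLKPVAAEDQKVLKIAM",
    "PF1505", "SPASE_I", 24L, "MKKASILLIIMLIASGLTIFNPKALGLEKYSTLT",
    "PF1938", "LIPOPROTEIN", 22L, "MRRATYAFALLAILVLGVVASGCIGGGTTTPT",
    "PF1408", "LIPOPROTEIN", 22L, "MKKGLLAILLVGVMVLGTFGSGCIGGGTQTQT",
    "PF0119", "LIPOPROTEIN", 20L, "MKHKAVFLLVVLISGVLASGCIGGETKETQ",
    "PF1774", "LIPOPROTEIN", 18L, "MKRAIPVFLLIVLVWISGCIGGGTSTIP",
    "PF1695", "LIPOPROTEIN", 21L, "MRKVGITLSVVALVIMGFVAGCIGGTQTQGE",
    "PF0337", "CLASS_III", 4L, "MKKGAIGIGTLIVFIAMVLVAAVAAGVLI",
    "PF0287", "CLASS_III", 5L, "MNKKGLTVLFIAIMLLSVVPVHFVS",
    "PF1304", "CLASS_III", 4L, "MRRGFIINSTLLILIIPLLLLAATYAEI"
  )
}

ref_proteins <- function() ref_fragments()[, c("id", "sequence")]

ref_calls <- function(params = sp_classifier_params()) {
  classify_signal_peptides(ref_proteins(), params)
}
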