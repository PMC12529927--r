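# shared guide fixtures (miRBase guide-strand sequences)
let7a  <- MirnaGuide("let-7a",  "UGAGGUAGUAGGUUGUAUAGUU")
mir155 <- MirnaGuide("miR-155", "UUAAUGCUAAUCGUGAUAGGGGU")
mir124 <- MirnaGuide("miR-124", "UAAGGCACGCGGUGAAUGCCAA")

rnaComp1 <- function(x) chartr("ACGU", "UGCA", x)

randRead <- function(n, len = 40L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}
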