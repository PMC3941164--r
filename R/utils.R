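stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "methanodiv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

DNA_BASES <- c("A", "C", "G", "T")
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

alphabet_chars <- function(alphabet) {
  switch(alphabet,
    dna = c(DNA_BASES, "N", "-"),
    protein = c(AA_RESIDUES, "X", "-"),
    stopf("unknown alphabet '%s'", alphabet)
  )
}

# informative symbols = everything except the gap and the ambiguity code
ambiguity_char <- function(alphabet) if (alphabet == "dna") "N" else "X"

`%||%` <- function(a, b) if (is.null(a)) b else a
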