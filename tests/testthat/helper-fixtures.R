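# Shared fixtures, built in code at test time.

# minimal valid variant row(s)
make_variants <- function(n = 1, ...) {
  args <- list(...)
  base <- data.frame(
    chrom = rep("sim1", n), pos = seq_len(n) * 100L, ref = rep("C", n),
    alt = rep("T", n), alt_support_tumor = rep(5L, n),
    depth_tumor = rep(20L, n), stringsAsFactors = FALSE)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  variant_table(base)
}

# two-signature matrix with orthogonal support for exact recovery checks
two_sig_matrix <- function() {
  labs <- context_labels()
  m <- matrix(0, 96, 2, dimnames = list(labs, c("SigA", "SigB")))
  m[1:48, 1] <- 1 / 48
  m[49:96, 2] <- 1 / 48
  signature_matrix(m)
}

# named spectrum from a numeric 96-vector
as_spectrum <- function(x) {
  names(x) <- context_labels()
  x
}
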