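# shared in-code fixtures for the test suite

# minimal two-residue, two-chain structure with CA/CB at chosen distances
twoResidueStructure <- function(dCA, dCB = dCA, residA = "LYS",
                                residB = "LYS") {
  atoms <- data.frame(
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L),
    resid = c(residA, residA, residB, residB),
    elety = c("CA", "CB", "CA", "CB"),
    x = c(0, 0, dCA, dCB), y = c(0, 1.5, 0, 1.5), z = 0,
    stringsAsFactors = FALSE)
  XLStructure("pair", atoms)
}

# a random CA-only structure of n residues on one chain
randomStructure <- function(n, seed = 1, id = "rand", chain = "A") {
  set.seed(seed)
  XLStructure(id, data.frame(
    chain = chain, resno = seq_len(n), resid = "ALA", elety = "CA",
    x = round(stats::rnorm(n, 0, 10), 3),
    y = round(stats::rnorm(n, 0, 10), 3),
    z = round(stats::rnorm(n, 0, 10), 3),
    stringsAsFactors = FALSE))
}

# one-row cross-link record
linkRow <- function(pa, ra, pb, rb, linker = "DSS",
                    condition = "both", approach = 1L) {
  data.frame(protein_a = pa, res_a = as.integer(ra),
             protein_b = pb, res_b = as.integer(rb),
             linker = linker, condition = condition,
             approach = as.integer(approach), stringsAsFactors = FALSE)
}

# random proper rotation matrix
randomRotationFixture <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# apply a rigid transform to every atom of a structure
transformStructure <- function(s, R, t) {
  a <- atomTable(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  XLStructure(structureId(s), a)
}
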