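# Hand-built fixtures, constructed in code so every expected value is
# enumerable by eye.

# Minimal paired design: 2 labeled + 2 control replicates, 3 fractions on a
# symmetric grid around 1.70 g/ml.
toy_fractions <- function(substrate = "bicarbonate") {
  reps <- c(L1 = "labeled", L2 = "labeled", C1 = "control", C2 = "control")
  do.call(rbind, lapply(names(reps), function(r) {
    data.frame(replicate = r, treatment = reps[[r]], substrate = substrate,
               fraction = 1:3, density = c(1.72, 1.70, 1.68),
               total_copies = 1e6)
  }))
}

# counts: per-OTU vector of length 3 recycled over the 4 replicates, or a
# named list keyed "replicate" -> 3-vector
toy_dataset <- function(counts_by_otu, substrate = "bicarbonate",
                        taxonomy = NULL) {
  fr <- toy_fractions(substrate)
  keys <- library_key(fr)
  mat <- matrix(0L, length(counts_by_otu), length(keys),
                dimnames = list(names(counts_by_otu), keys))
  for (otu in names(counts_by_otu)) {
    spec <- counts_by_otu[[otu]]
    for (r in unique(fr$replicate)) {
      v <- if (is.list(spec)) spec[[r]] else spec
      sel <- fr$replicate == r
      mat[otu, keys[sel]] <- as.integer(v)
    }
  }
  qsip_dataset(fr, mat, taxonomy = taxonomy)
}

# EAF computed by the chain of closed-form model equations, written out
# independently of the package internals; the reference oracle for eaf_point.
oracle_eaf <- function(w_light, w_lab) {
  gc <- (w_light - 1.646057) / 0.083506
  m_light <- 0.496 * gc + 307.691
  m_heavymax <- m_light + 9.974564 - 0.4987282 * gc
  m_lab <- w_lab / w_light * m_light
  (m_lab - m_light) / (m_heavymax - m_light) * (1 - 0.01111233)
}
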