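# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing binary is stored.

as_long_counts <- function(m, value = "count") {
  out <- tibble::tibble(
    gene_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)))
  out[[value]] <- as.vector(m)
  out
}

mk_matrix <- function(seed, n_genes, n_samples, f) {
  set.seed(seed)
  m <- f(n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# Five count matrices covering plain NB noise, composition bias, excess
# zeros, a 10-gene toy with one 8-fold inflated gene, and a wide
# abundance range.
tmm_fixture_matrices <- function() {
  list(
    nb = mk_matrix(101, 200, 6, function(g, s)
      matrix(rnbinom(g * s, mu = 200, size = 10), g, s)),
    biased = mk_matrix(102, 150, 4, function(g, s) {
      m <- matrix(rnbinom(g * s, mu = 100, size = 5), g, s)
      m[1:10, 1] <- m[1:10, 1] * 8
      m
    }),
    zeros = mk_matrix(103, 100, 5, function(g, s) {
      m <- matrix(rnbinom(g * s, mu = 50, size = 2), g, s)
      m[sample(length(m), 80)] <- 0
      m
    }),
    toy10 = mk_matrix(104, 10, 2, function(g, s) {
      m <- matrix(rpois(g * s, 100), g, s)
      m[1, 2] <- m[1, 2] * 8
      m
    }),
    wide = mk_matrix(105, 300, 8, function(g, s)
      matrix(rnbinom(g * s, mu = exp(runif(g * s, 2, 7)), size = 3), g, s)))
}

# Scaling factors from the reference TMM implementation, run once on the
# fixtures above and frozen (independent oracle for the from-scratch TMM).
tmm_reference_factors <- list(
  nb = c(0.988127223508097, 1.010907821265123, 0.995663821632723,
         1.010461011174265, 1.016255831335148, 0.979129736514007),
  biased = c(0.754166510434277, 1.082648211503425, 1.110924349843697,
             1.102455092832993),
  zeros = c(1.102052387539856, 0.957465171444650, 0.871472472632441,
            1.069907213238574, 1.016424175353617),
  toy10 = c(1.361229791006046, 0.734629822684772),
  wide = c(1.037013944826048, 0.896441901427747, 0.962504821733567,
           1.129407733122124, 0.995301652838311, 1.182328843724955,
           0.909629083929381, 0.924447467248672))

# Balanced 2x2 design with 2 replicates per cell; hand-computed sequential
# sums of squares: provenance 32, gene 2, interaction 0, residual 8.
anova_fixture <- function() {
  tibble::tibble(
    provenance = rep(c("north", "north", "south", "south"), each = 2),
    gene_model = rep(c("m1", "m2", "m1", "m2"), each = 2),
    total_cn = c(1, 3, 2, 4, 5, 7, 6, 8))
}

# A small 3-region panel on two contigs.
toy_panel <- function() {
  tibble::tibble(
    region_id = c("r1", "r2", "r3"),
    contig = c("c1", "c1", "c2"),
    start = c(0L, 200L, 50L),
    end = c(100L, 300L, 150L),
    gene_id = c("geneA", "geneB", "geneC"),
    region_class = c("acetophenone_target", "internal_standard",
                     "internal_standard"),
    length = c(100L, 100L, 100L))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
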