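# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small genome: fast to simulate, dense enough that the 10-marker
# smoothing window (~1.5 Mb) stays below the 4 Mb fragment scale, and large
# enough (180 Mb) that the forced selectable-locus fragment does not eat
# the retention budget.
small_genome <- function() fixture("small_genome", function() {
  example_genome(n_autosomes = 2, autosome_length = 6e7, sex_length = 6e7,
                 n_markers = 1200, n_genes = 60)
})

# Default-scale panel: 200 genes x 2000 markers x 79 clones at the
# documented noise levels; used for recovery and attenuation tests.
default_panel <- function() fixture("default_panel", function() {
  genome <- example_genome()
  config <- sim_config(seed = 42)
  list(genome = genome, config = config,
       panel = simulate_panel(genome, config))
})

# Nearest-marker cis fits over a panel: planted vs estimated alpha. Genes
# whose nearest marker never varies across clones are unidentifiable and
# come back as NA.
nearest_marker_fits <- function(genome, panel) {
  nm <- nearest_marker(genome)
  est <- vapply(seq_len(nrow(genome$genes)), function(i) {
    x <- panel$normalized$values[nm[genome$genes$id[i]], ]
    if (stats::sd(x) < 1e-9) return(NA_real_)
    fit_dosage_model(panel$expression$values[i, ], x)$alpha
  }, numeric(1))
  data.frame(gene = genome$genes$id, marker = unname(nm[genome$genes$id]),
             alpha = est, planted = panel$truth$gene_alpha$alpha,
             stringsAsFactors = FALSE)
}

# Expression matrix of pure noise over an existing panel's clones (global
# null: no dosage effect anywhere).
null_expression <- function(genome, truth, sd = 0.1, seed = 99) {
  set.seed(seed)
  y <- matrix(stats::rnorm(nrow(genome$genes) * length(truth$clone_ids), 0, sd),
              nrow(genome$genes), length(truth$clone_ids))
  colnames(y) <- truth$clone_ids
  expression_matrix(y, genome$genes)
}
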