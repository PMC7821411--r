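# Shared fixture builders. Everything is generated in code, seeded.

random_expression <- function(n_genes = 20, n_samples = 10, seed = 1,
                              low = NULL, high = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  if (!is.null(low)) {
    rng <- range(v)
    v <- low + (high - low) * (v - rng[1]) / (rng[2] - rng[1])
  }
  expression_matrix(v,
                    gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    sample_ids = sprintf("s%03d", seq_len(n_samples)))
}

unit_expression <- function(n_genes = 20, n_samples = 10, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(n_genes * n_samples), n_genes, n_samples)
  expression_matrix(v,
                    gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    sample_ids = sprintf("s%03d", seq_len(n_samples)))
}

# Random small network with mixed activations; the narrowest layer is the
# bottleneck, so the encoder sub-network is layers 1..bottleneck_index.
random_network <- function(input_dim, widths, seed = 1,
                           activations = NULL) {
  if (is.null(activations)) {
    set.seed(seed + 7777)
    activations <- sample(c("sigmoid", "linear"), length(widths),
                          replace = TRUE)
  }
  layers <- Map(function(w, a) layer_spec(w, a), widths, activations)
  init_network(input_dim, layers, seed = seed)
}

# Manually assembled single-path network for hand-computed examples.
manual_network <- function(Ws, bs, activations) {
  layers <- Map(function(W, a) layer_spec(nrow(W), a), Ws, activations)
  params <- init_network(ncol(Ws[[1]]), layers, seed = 1)
  for (l in seq_along(Ws)) {
    params$layers[[l]]$W <- Ws[[l]]
    params$layers[[l]]$b <- bs[[l]]
  }
  params
}

sigmoid <- function(z) 1 / (1 + exp(-z))
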