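# Expression-matrix simulator for the four-group photoconversion design:
# leader, follower, photoconverted control (IR) and non-photoconverted
# control (NG), n replicates each. Gene classes: null, leader-up,
# follower-up, and photoconversion-artifact genes whose shift appears in
# both the leader and the IR samples (so the L-F and IR-NG contrasts move
# together, mimicking an expression change caused by photoconversion
# rather than by leader biology).

#' Group labels of the photoconversion expression design
#' @export
EXPRESSION_GROUPS <- c("leader", "follower", "ctrl_photo", "ctrl_nonphoto")

#' Specification of a simulated expression experiment
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per group (default 3, giving 12 samples).
#' @param baseline_mean,baseline_sd mean and standard deviation of the
#'   baseline log2 expression; all values are i.i.d. Gaussian around the
#'   baseline before effects are added.
#' @param delta effect size in log2 units (>= 0) added to the affected
#'   samples of non-null genes.
#' @param f_null,f_leader_up,f_follower_up,f_artifact gene-class fractions;
#'   must sum to 1. Artifact genes add `delta` to both the leader and the
#'   photoconverted-control samples.
#' @param seed integer seed; required.
#' @return Object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 2000, n_reps = 3,
                                baseline_mean = 7, baseline_sd = 0.25,
                                delta = 1,
                                f_null = 0.85, f_leader_up = 0.05,
                                f_follower_up = 0.05, f_artifact = 0.05,
                                seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_number(n_genes, "n_genes", min = 1, integer = TRUE)
  check_number(n_reps, "n_reps", min = 2, integer = TRUE)
  check_number(baseline_sd, "baseline_sd", min = 0)
  check_number(delta, "delta", min = 0)
  fr <- c(f_null, f_leader_up, f_follower_up, f_artifact)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("gene-class fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         delta = delta, f_null = f_null, f_leader_up = f_leader_up,
         f_follower_up = f_follower_up, f_artifact = f_artifact,
         seed = as.integer(seed)),
    class = "expression_sim_spec")
}

#' Simulate an expression matrix with planted effects
#'
#' @param spec an [expression_sim_spec()].
#' @return A list with:
#' \describe{
#'   \item{matrix}{numeric gene x sample matrix (log2 scale), rownames
#'     `gene_0001`..., colnames `<group>_<replicate>`.}
#'   \item{design}{data frame `sample_id`, `group`, `replicate`.}
#'   \item{truth}{data frame `gene_id`, `label` with label in
#'     `c("null", "leader_up", "follower_up", "artifact")`.}
#'   \item{spec}{the input spec.}
#' }
#' @examples
#' sim <- simulate_expression(expression_sim_spec(n_genes = 50, seed = 3))
#' table(sim$truth$label)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  G <- spec$n_genes; n <- spec$n_reps
  counts <- c(leader_up = floor(spec$f_leader_up * G),
              follower_up = floor(spec$f_follower_up * G),
              artifact = floor(spec$f_artifact * G))
  counts <- c(null = G - sum(counts), counts)
  labels <- rep(names(counts), counts)

  design <- data.frame(
    sample_id = paste(rep(EXPRESSION_GROUPS, each = n), seq_len(n), sep = "_"),
    group = rep(EXPRESSION_GROUPS, each = n),
    replicate = rep(seq_len(n), times = 4))

  with_seed(spec$seed, {
    m <- matrix(rnorm(G * 4 * n, mean = spec$baseline_mean,
                      sd = spec$baseline_sd),
                nrow = G, ncol = 4 * n,
                dimnames = list(sprintf("gene_%04d", seq_len(G)),
                                design$sample_id))
    leader_cols <- design$group == "leader"
    follower_cols <- design$group == "follower"
    photo_cols <- design$group == "ctrl_photo"
    m[labels == "leader_up", leader_cols] <-
      m[labels == "leader_up", leader_cols] + spec$delta
    m[labels == "follower_up", follower_cols] <-
      m[labels == "follower_up", follower_cols] + spec$delta
    m[labels == "artifact", leader_cols | photo_cols] <-
      m[labels == "artifact", leader_cols | photo_cols] + spec$delta
    list(matrix = m, design = design,
         truth = data.frame(gene_id = rownames(m), label = labels),
         spec = spec)
  })
}
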