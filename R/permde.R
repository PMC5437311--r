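# Paired-difference permutation test for differential expression on the
# four-group design {leader, follower, ctrl_photo (IR), ctrl_nonphoto
# (NG)}, n replicates each (default 3). For each gene, all n x n pairwise
# differences leader_i - follower_j form the treatment set and all n x n
# pairwise IR_i - NG_j differences form the control set. Two statistics are
# computed: a one-sample t of the treatment differences against zero, and a
# two-sample t of the treatment differences against the *absolute* control
# differences. The permutation reassigns the pooled 2n^2 signed differences
# between the two roles; a gene's p-value is the fraction of permutations
# whose statistics jointly meet or exceed the observed ones. Because the
# control contrast captures expression changes caused by photoconversion
# itself, a gene whose shift is also present in the IR-NG contrast (an
# artifact gene) cannot beat the control differences and is not selected.

# ---- design handling -------------------------------------------------

check_design <- function(mat, design) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(design))) {
    stop("`design` needs columns sample_id and group", call. = FALSE)
  }
  if (!all(design$group %in% EXPRESSION_GROUPS)) {
    stop("`design$group` must be one of: ",
         paste(EXPRESSION_GROUPS, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(design$group, levels = EXPRESSION_GROUPS))
  if (any(tab == 0)) {
    stop("design is incomplete: missing group(s) ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  }
  if (length(unique(tab)) != 1) {
    stop("all groups must have the same number of replicates", call. = FALSE)
  }
  if (!all(design$sample_id %in% colnames(mat))) {
    stop("every design sample_id must be a column of the matrix",
         call. = FALSE)
  }
  invisible(as.integer(tab[1]))
}

group_cols <- function(mat, design, group) {
  mat[, design$sample_id[design$group == group], drop = FALSE]
}

# ---- difference pairs ------------------------------------------------

#' All pairwise treatment and control expression differences
#'
#' For `n` replicates per group, forms the `n^2` pairwise differences
#' between the treatment groups (direction `"leader"`: leader_i -
#' follower_j; direction `"follower"`: follower_i - leader_j) and the `n^2`
#' pairwise differences ctrl_photo_i - ctrl_nonphoto_j, stored signed (the
#' absolute value is applied to the control role at statistic time).
#'
#' @param mat numeric gene x sample matrix (log2 scale), columns named by
#'   `design$sample_id`.
#' @param design data frame `sample_id`, `group` (groups as in
#'   [EXPRESSION_GROUPS]), `replicate`.
#' @param direction `"leader"` or `"follower"`.
#' @return list of class `difference_pairs` with matrices `treatment` and
#'   `control` (genes x n^2, signed) and attributes `n_pairs`, `direction`.
#' @export
make_difference_pairs <- function(mat, design,
                                  direction = c("leader", "follower")) {
  direction <- match.arg(direction)
  mat <- as.matrix(mat)
  n <- check_design(mat, design)
  L <- group_cols(mat, design, "leader")
  F_ <- group_cols(mat, design, "follower")
  IR <- group_cols(mat, design, "ctrl_photo")
  NG <- group_cols(mat, design, "ctrl_nonphoto")

  pairwise <- function(A, B) {
    # all columns of A minus all columns of B -> G x (n*n)
    out <- matrix(NA_real_, nrow(A), n * n)
    k <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      k <- k + 1
      out[, k] <- A[, i] - B[, j]
    }
    rownames(out) <- rownames(A)
    out
  }
  treatment <- if (direction == "leader") pairwise(L, F_) else pairwise(F_, L)
  structure(list(treatment = treatment, control = pairwise(IR, NG)),
            class = "difference_pairs", n_pairs = n * n,
            direction = direction)
}

# ---- t statistics ----------------------------------------------------

# Row-wise one-sample t against 0. Zero-variance convention: +/-Inf by the
# sign of the mean, 0 when the mean is also 0.
t_one_vec <- function(M) {
  m <- ncol(M)
  mu <- rowMeans(M)
  v <- rowSums((M - mu)^2) / (m - 1)
  t <- ifelse(v > 0, mu / sqrt(v / m), sign(mu) * Inf)
  t[v == 0 & mu == 0] <- 0
  t
}

# Row-wise two-sample t (pooled variance by default, Welch optional) of A
# against B; same zero-variance convention.
t_two_vec <- function(A, B, welch = FALSE) {
  m <- ncol(A); n <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (m - 1)
  vb <- rowSums((B - mb)^2) / (n - 1)
  se2 <- if (welch) va / m + vb / n
         else (((m - 1) * va + (n - 1) * vb) / (m + n - 2)) * (1 / m + 1 / n)
  num <- ma - mb
  t <- ifelse(se2 > 0, num / sqrt(se2), sign(num) * Inf)
  t[se2 == 0 & num == 0] <- 0
  t
}

#' Observed test statistics of difference pairs
#'
#' @param pairs a [make_difference_pairs()] result.
#' @param welch use the Welch (unpooled) two-sample t instead of the
#'   pooled-variance form.
#' @return data frame with `t_one` (one-sample t of the treatment
#'   differences against zero) and `t_two` (two-sample t of the treatment
#'   differences against the absolute control differences), one row per
#'   gene. Degenerate zero-variance cases give `+/-Inf` (0 when the
#'   numerator is also 0).
#' @export
gene_stats <- function(pairs, welch = FALSE) {
  stopifnot(inherits(pairs, "difference_pairs"))
  data.frame(t_one = t_one_vec(pairs$treatment),
             t_two = t_two_vec(pairs$treatment, abs(pairs$control), welch),
             row.names = rownames(pairs$treatment))
}

# ---- permutation machinery -------------------------------------------

#' Permutation-test parameters
#'
#' @param B number of sampled permutations (default 500).
#' @param alpha selection threshold on the permutation p-value.
#' @param seed integer seed for the permutation plan.
#' @param scheme permutation scheme used by [run_de()]:
#'   `"status"` (default) relabels leader/IR within the photoconverted
#'   samples and follower/NG within the non-photoconverted samples and
#'   rebuilds the difference pairs per permutation — exactly exchangeable
#'   under the null that leader/follower differences are explained by
#'   photoconversion; `"pairs"` reassigns the pooled `2 n^2` signed
#'   difference values between the treatment and control roles and uses
#'   the single joint-exceedance count (the difference-level formulation;
#'   see the methods vignette for why it is not the default).
#' @param exhaustive (`"pairs"` scheme only) force full enumeration of the
#'   `choose(2 n^2, n^2)` role assignments when that count does not exceed
#'   `exhaustive_cap`.
#' @param exhaustive_cap enumeration cap.
#' @param welch use Welch's two-sample t.
#' @return object of class `perm_params`.
#' @export
perm_params <- function(B = 500, alpha = 0.05, seed = 1,
                        scheme = c("status", "pairs"),
                        exhaustive = FALSE, exhaustive_cap = 2e5,
                        welch = FALSE) {
  check_number(B, "B", min = 1, integer = TRUE)
  check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  check_number(seed, "seed", integer = TRUE)
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 scheme = match.arg(scheme),
                 exhaustive = isTRUE(exhaustive),
                 exhaustive_cap = exhaustive_cap, welch = isTRUE(welch)),
            class = "perm_params")
}

# A permutation plan: each row of `idx` lists the positions (of the pooled
# 2m signed differences) assigned to the treatment role. Sampled plans draw
# distinct assignments without replacement whenever the assignment space is
# comfortably larger than B.
permutation_plan <- function(n_pairs, params) {
  tot <- 2L * n_pairs
  n_comb <- choose(tot, n_pairs)
  if (params$exhaustive && n_comb <= params$exhaustive_cap) {
    return(list(idx = t(utils::combn(tot, n_pairs)), exhaustive = TRUE,
                n_total = n_comb))
  }
  with_seed(params$seed, {
    dedupe <- n_comb > 2 * params$B
    seen <- new.env(hash = TRUE)
    rows <- vector("list", params$B)
    got <- 0L; tries <- 0L
    while (got < params$B && tries < 1000L * params$B) {
      tries <- tries + 1L
      s <- sort(sample.int(tot, n_pairs))
      if (dedupe) {
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
      }
      got <- got + 1L
      rows[[got]] <- s
    }
    list(idx = do.call(rbind, rows[seq_len(got)]), exhaustive = FALSE,
         n_total = n_comb)
  })
}

# Count permutations whose statistics jointly meet or exceed the observed
# ones (ties count as exceedance; Inf vs Inf resolves as a tie).
perm_exceed_counts <- function(pool, t1_obs, t2_obs, idx, welch) {
  count <- integer(length(t1_obs))
  all_pos <- seq_len(ncol(pool))
  for (b in seq_len(nrow(idx))) {
    sel <- idx[b, ]
    Tp <- pool[, sel, drop = FALSE]
    Cp <- abs(pool[, setdiff(all_pos, sel), drop = FALSE])
    hit <- t_one_vec(Tp) >= t1_obs & t_two_vec(Tp, Cp, welch) >= t2_obs
    count <- count + hit
  }
  count
}

#' Joint-exceedance permutation p-values
#'
#' Pools the `2 n^2` signed difference values of each gene, repeatedly
#' reassigns `n^2` of them to the treatment role (used signed) and `n^2` to
#' the control role (absolute value applied), recomputes both t statistics,
#' and counts the permutations in which both permuted statistics meet or
#' exceed the observed ones. Sampled p-values use add-one smoothing,
#' `p = (count + 1) / (B + 1)`, so `p > 0` always; with
#' `params$exhaustive` and a feasible assignment count the exact fraction
#' over all assignments (identity included) is returned. The same
#' assignment sequence is applied to every gene.
#'
#' @param pairs a [make_difference_pairs()] result (one or many genes).
#' @param params a [perm_params()].
#' @return numeric vector of p-values in (0, 1], one per gene.
#' @export
permutation_p <- function(pairs, params = perm_params()) {
  stopifnot(inherits(pairs, "difference_pairs"),
            inherits(params, "perm_params"))
  obs <- gene_stats(pairs, params$welch)
  pool <- cbind(pairs$treatment, pairs$control)
  plan <- permutation_plan(attr(pairs, "n_pairs"), params)
  count <- perm_exceed_counts(pool, obs$t_one, obs$t_two, plan$idx,
                              params$welch)
  if (plan$exhaustive) count / nrow(plan$idx)
  else (count + 1) / (nrow(plan$idx) + 1)
}

# ---- photoconversion-status permutation engine -----------------------

# The leader (L) and photoconverted-control (IR) samples are both
# photoconverted populations; the follower (F) and non-photoconverted
# control (NG) samples are not. The composite null "leader/follower
# differences are explained by photoconversion status" is therefore
# exactly exchangeable under relabelling L <-> IR within the 2n
# photoconverted samples and F <-> NG within the 2n non-photoconverted
# samples: choose(2n, n)^2 assignments (400 for n = 3). Both the global
# null and artifact genes (equal shift in L and IR) satisfy this null.

# Enumerate or sample the status-preserving relabellings. Each row: the
# columns taking the L role (n of the photo columns) followed by the
# columns taking the F role (n of the non-photo columns). The first row
# is the identity assignment.
status_plan <- function(photo_cols, nonphoto_cols, n, params) {
  ch <- utils::combn(length(photo_cols), n)
  total <- ncol(ch)^2
  if (total <= params$B) {
    idx <- expand.grid(a = seq_len(ncol(ch)), b = seq_len(ncol(ch)))
    plan <- cbind(t(ch[, idx$a, drop = FALSE]), t(ch[, idx$b, drop = FALSE]))
    # put the identity assignment (columns 1..n of each block) first
    id <- which(idx$a == 1 & idx$b == 1)
    plan <- plan[c(id, setdiff(seq_len(total), id)), , drop = FALSE]
    exhaustive <- TRUE
  } else {
    plan <- with_seed(params$seed, {
      seen <- new.env(hash = TRUE)
      rows <- list(seq_len(2 * n))  # identity first
      seen[[paste(rows[[1]], collapse = ",")]] <- TRUE
      while (length(rows) < params$B) {
        s <- c(sort(sample.int(length(photo_cols), n)),
               sort(sample.int(length(nonphoto_cols), n)))
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        rows[[length(rows) + 1]] <- s
      }
      do.call(rbind, rows)
    })
    exhaustive <- FALSE
  }
  list(idx = plan, exhaustive = exhaustive, total = total)
}

# For one group-label assignment (columns of each group), the two
# statistics per gene and direction.
stats_for_assignment <- function(mat, gl, gf, gir, gng, n, welch) {
  Tm <- mat[, rep(gl, each = n), drop = FALSE] -
    mat[, rep(gf, times = n), drop = FALSE]
  aC <- abs(mat[, rep(gir, each = n), drop = FALSE] -
              mat[, rep(gng, times = n), drop = FALSE])
  list(t1L = t_one_vec(Tm), t2L = t_two_vec(Tm, aC, welch),
       t1F = t_one_vec(-Tm), t2F = t_two_vec(-Tm, aC, welch))
}

# row-wise proportion of values >= each value (self included): a
# calibrated per-permutation marginal p in (0, 1]
row_exceed_prop <- function(M) {
  t(apply(M, 1, function(x) rank(-x, ties.method = "max"))) / ncol(M)
}

# Status-scheme p-values. For each direction, marginal permutation
# p-values of the one- and two-sample t are combined as S = max(p1, p2)
# ("both hypotheses must hold"); S is then calibrated against its own
# permutation distribution (single-step max-p calibration), so the joint
# p-value is exact under the status-exchangeable null rather than
# conservative (plain intersection-union) or anti-conservative (raw
# joint exceedance counting).
de_status <- function(mat, design, params) {
  n <- check_design(mat, design)
  cols <- match(design$sample_id, colnames(mat))
  grp <- split(cols, factor(design$group, levels = EXPRESSION_GROUPS))
  photo <- c(grp$leader, grp$ctrl_photo)
  nonphoto <- c(grp$follower, grp$ctrl_nonphoto)
  plan <- status_plan(photo, nonphoto, n, params)
  B <- nrow(plan$idx)
  G <- nrow(mat)
  perm <- list(t1L = matrix(NA_real_, G, B), t2L = matrix(NA_real_, G, B),
               t1F = matrix(NA_real_, G, B), t2F = matrix(NA_real_, G, B))
  for (b in seq_len(B)) {
    gl <- photo[plan$idx[b, seq_len(n)]]
    gir <- setdiff(photo, gl)
    gf <- nonphoto[plan$idx[b, n + seq_len(n)]]
    gng <- setdiff(nonphoto, gf)
    st <- stats_for_assignment(mat, gl, gf, gir, gng, n, params$welch)
    for (k in names(perm)) perm[[k]][, b] <- st[[k]]
  }
  # row 1 of the plan is the identity: the observed statistics
  obs <- lapply(perm, function(m) m[, 1])
  joint_p <- function(t1o, t2o, T1, T2) {
    if (plan$exhaustive) {
      # observed assignment is part of the ensemble: exact fractions
      p1 <- rowSums(T1 >= t1o) / B
      p2 <- rowSums(T2 >= t2o) / B
      S_obs <- pmax(p1, p2)
      S_perm <- pmax(row_exceed_prop(T1), row_exceed_prop(T2))
      p <- rowSums(S_perm <= S_obs) / B
    } else {
      p1 <- (rowSums(T1[, -1, drop = FALSE] >= t1o) + 1) / B
      p2 <- (rowSums(T2[, -1, drop = FALSE] >= t2o) + 1) / B
      S_obs <- pmax(p1, p2)
      S_perm <- pmax(row_exceed_prop(T1), row_exceed_prop(T2))
      p <- (rowSums(S_perm[, -1, drop = FALSE] <= S_obs) + 1) / B
    }
    list(p = p, p1 = p1, p2 = p2)
  }
  list(leader = joint_p(obs$t1L, obs$t2L, perm$t1L, perm$t2L),
       follower = joint_p(obs$t1F, obs$t2F, perm$t1F, perm$t2F),
       obs = obs, plan = plan, B = B)
}

#' Permutation differential-expression test on the four-group design
#'
#' Tests, for every gene, whether the leader-vs-follower expression
#' differences (a) exceed zero and (b) exceed the absolute differences of
#' the photoconversion control contrast (IR vs NG), by permutation;
#' `p_leader` tests the leader-minus-follower direction, `p_follower` the
#' reverse. Genes with `p < alpha` are flagged as selected. Genes whose
#' shift is also present in the control contrast (photoconversion
#' artifacts) fail test (b) and are not selected.
#'
#' With the default `scheme = "status"`, group labels are permuted within
#' photoconversion status (leader <-> IR among the photoconverted
#' samples, follower <-> NG among the non-photoconverted ones; all
#' `choose(2n, n)^2` relabellings are enumerated when they do not exceed
#' `B`). This null is exactly exchangeable both for genes with no group
#' structure and for photoconversion-artifact genes, so either is
#' selected at rate `alpha` while leader-specific genes are detected.
#' The marginal permutation p-values of the two statistics are combined
#' as `S = max(p1, p2)` and `S` is calibrated against its own permutation
#' distribution, giving an exact joint p-value. With `scheme = "pairs"`
#' the difference-level joint-exceedance count of [permutation_p()] is
#' used instead. One shared permutation plan (the same reassignments for
#' every gene and both directions) is drawn from `params$seed`.
#' Benjamini-Hochberg adjusted q-values are emitted as supplementary
#' columns but never drive selection, which uses the raw p-values.
#'
#' @param mat normalized, gene-level numeric matrix (log2 scale), columns
#'   named by `design$sample_id`.
#' @param design data frame `sample_id`, `group`, `replicate`.
#' @param params a [perm_params()].
#' @return data frame of class `de_result` with columns `gene_id`,
#'   `t_one_L`, `t_two_L`, `p_leader`, `p_follower`, `selected_leader`,
#'   `selected_follower`, `bh_q_leader`, `bh_q_follower`; metadata
#'   (B, alpha, seed, scheme, permutation-plan digest) in the `meta`
#'   attribute.
#' @examples
#' sim <- simulate_expression(expression_sim_spec(n_genes = 20, seed = 1))
#' res <- run_de(sim$matrix, sim$design, perm_params(B = 99, seed = 1))
#' head(res)
#' @export
run_de <- function(mat, design, params = perm_params()) {
  stopifnot(inherits(params, "perm_params"))
  mat <- as.matrix(mat)

  if (params$scheme == "status") {
    res <- de_status(mat, design, params)
    p_leader <- res$leader$p
    p_follower <- res$follower$p
    t_one_L <- res$obs$t1L; t_two_L <- res$obs$t2L
    B_used <- res$B
    plan_obj <- res$plan$idx
    exhaustive <- res$plan$exhaustive
  } else {
    pairs_l <- make_difference_pairs(mat, design, "leader")
    pairs_f <- make_difference_pairs(mat, design, "follower")
    plan <- permutation_plan(attr(pairs_l, "n_pairs"), params)
    p_for <- function(pairs) {
      obs <- gene_stats(pairs, params$welch)
      pool <- cbind(pairs$treatment, pairs$control)
      count <- perm_exceed_counts(pool, obs$t_one, obs$t_two, plan$idx,
                                  params$welch)
      p <- if (plan$exhaustive) count / nrow(plan$idx)
           else (count + 1) / (nrow(plan$idx) + 1)
      list(p = p, obs = obs)
    }
    resl <- p_for(pairs_l)
    resf <- p_for(pairs_f)
    p_leader <- resl$p; p_follower <- resf$p
    t_one_L <- resl$obs$t_one; t_two_L <- resl$obs$t_two
    B_used <- nrow(plan$idx)
    plan_obj <- plan$idx
    exhaustive <- plan$exhaustive
  }

  out <- data.frame(
    gene_id = if (!is.null(rownames(mat))) rownames(mat)
              else sprintf("gene_%04d", seq_len(nrow(mat))),
    t_one_L = t_one_L, t_two_L = t_two_L,
    p_leader = p_leader, p_follower = p_follower,
    selected_leader = p_leader < params$alpha,
    selected_follower = p_follower < params$alpha,
    bh_q_leader = p.adjust(p_leader, "BH"),
    bh_q_follower = p.adjust(p_follower, "BH"),
    row.names = NULL)
  plan_digest <- {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeBin(as.integer(plan_obj), tf)
    unname(tools::md5sum(tf))
  }
  structure(out, class = c("de_result", "data.frame"),
            meta = list(B = B_used, alpha = params$alpha,
                        seed = params$seed, scheme = params$scheme,
                        exhaustive = exhaustive,
                        welch = params$welch, plan_digest = plan_digest))
}
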