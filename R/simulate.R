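# Synthetic paired BCR/TCR cohorts with the statistical structure the
# analysis assumes, plus ground truth for recovery tests.

#' Configuration of the synthetic paired-cohort generator
#'
#' The defaults describe the reference simulation used throughout the
#' package's validation: 4 studies of 30 individuals with a strong shared
#' latent repertoire-size factor, a heavy-tailed (Zipf-like) abundance
#' distribution whose tail exponent is modulated by a second shared latent,
#' public clonotype pools shared across individuals, and 3 planted
#' B x T clonotype clusters (10 B and 20 T members each) whose presence and
#' proportions track one latent factor per individual and cluster, with
#' mutually similar (edit radius 2), motif-bearing member sequences.
#'
#' @param n_studies number of studies (default 4).
#' @param individuals_per_study individuals per study (default 30).
#' @param healthy_fraction fraction of individuals labelled `healthy` per
#'   study (default 1; clusters are planted regardless of condition).
#' @param mu_log_size,sigma_log_size mean and sd of log clonal volume per
#'   locus (defaults log(300) for IGH, log(500) for TRB; sd 0.4).
#' @param rho_size weight of the shared latent in log repertoire size
#'   (default 0.9; the induced between-chain correlation is `rho_size^2`).
#' @param alpha Zipf tail exponent of clonal abundances (default 1).
#' @param alpha_mod log-scale modulation sd of the exponent (default 0.15).
#' @param rho_div weight of the second shared latent in the exponent
#'   modulation (default 0.7).
#' @param public_size public pool sizes per locus (defaults 60 IGH,
#'   120 TRB).
#' @param public_incl_prob inclusion probability of a non-cluster public
#'   clonotype per individual (default 0.5).
#' @param k_clusters number of planted clusters (default 3; 0 disables
#'   planting).
#' @param cluster_size_b,cluster_size_t members per cluster (defaults 10
#'   and 20); `k_clusters * cluster_size` must not exceed the pool.
#' @param lambda factor loading of the cluster latent on member proportions
#'   (default 2.5, a strong signal).
#' @param cluster_noise_sd member-level noise sd on the softplus scale
#'   (default 0.1).
#' @param presence_coupling logit-scale loading of the cluster latent on
#'   member inclusion (default 1.5), so that carrying a cluster's members is
#'   itself informative.
#' @param d_intra edit radius of cluster member sequences around the
#'   cluster seed sequence (default 2).
#' @param motifs character vector of planted motifs, one per cluster;
#'   `NULL` (default) draws random 4-mers.
#' @param cdr3_length_mean,cdr3_length_sd CDR3 length model per locus
#'   (defaults mean 16/14 for IGH/TRB, sd 2).
#' @param reads_per_clonotype average sequencing depth per clonotype
#'   (default 10).
#' @param assign_subsets label clonotypes with cell subsets (cluster
#'   members become memory subsets; default TRUE).
#' @param seed integer master seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_studies = 4,
                         individuals_per_study = 30,
                         healthy_fraction = 1,
                         mu_log_size = c(IGH = log(300), TRB = log(500)),
                         sigma_log_size = 0.4,
                         rho_size = 0.9,
                         alpha = 1,
                         alpha_mod = 0.15,
                         rho_div = 0.7,
                         public_size = c(IGH = 60, TRB = 120),
                         public_incl_prob = 0.5,
                         k_clusters = 3,
                         cluster_size_b = 10,
                         cluster_size_t = 20,
                         lambda = 2.5,
                         cluster_noise_sd = 0.1,
                         presence_coupling = 1.5,
                         d_intra = 2,
                         motifs = NULL,
                         cdr3_length_mean = c(IGH = 16, TRB = 14),
                         cdr3_length_sd = 2,
                         reads_per_clonotype = 10,
                         assign_subsets = TRUE,
                         seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(healthy_fraction, rho_size, rho_div, public_incl_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities/weights must lie in [0, 1]")
  if (k_clusters < 0) abort("k_clusters must be >= 0")
  if (k_clusters > 0) {
    if (k_clusters * cluster_size_b > public_size[["IGH"]] ||
        k_clusters * cluster_size_t > public_size[["TRB"]]) {
      abort("cluster sizes exceed public pool sizes")
    }
  }
  structure(cfg, class = "synth_config")
}

#' Sample random CDR3 amino-acid strings
#'
#' Strings start with `C`, end with `F` or `W`, and have interior residues
#' uniform over the 20-letter alphabet; lengths are normal, rounded, and
#' floored at 5.
#'
#' @param n number of sequences.
#' @param length_mean,length_sd length model.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return character vector of length `n`.
#' @export
sample_cdr3 <- function(n, length_mean = 14, length_sd = 2, seed = NULL) {
  run <- function() {
    lens <- pmax(5L, as.integer(round(rnorm(n, length_mean, length_sd))))
    interior <- sample(AA_ALPHABET, sum(lens - 2), replace = TRUE)
    ends <- sample(c("F", "W"), n, replace = TRUE)
    mids <- vapply(split(interior, rep.int(seq_len(n), lens - 2)),
                   paste, character(1), collapse = "")
    # split() orders groups by sorted integer index = original order
    paste0("C", mids[order(as.integer(names(mids)))], ends)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Mutate a CDR3 within a Levenshtein radius
#'
#' Applies a uniformly chosen number of edits (0..`max_edits`); each edit
#' is a substitution, insertion or deletion at a random interior position,
#' so the result stays within `max_edits` edit distance of the input.
#' Positions inside `protect` (a `c(start, end)` span, e.g. a planted
#' motif) are never edited.
#'
#' @param seed_seq the starting sequence.
#' @param max_edits maximum number of edits (must be < nchar(seed_seq)).
#' @param protect optional `c(start, end)` character span to leave intact.
#' @param indels allow insertions/deletions (default TRUE; FALSE keeps the
#'   length fixed, substitutions only).
#' @param seed optional integer seed.
#' @return the mutated sequence.
#' @export
mutate_within_ld <- function(seed_seq, max_edits, protect = NULL,
                             indels = TRUE, seed = NULL) {
  if (max_edits < 0) abort("max_edits must be >= 0")
  if (max_edits >= nchar(seed_seq)) abort("max_edits must be smaller than the sequence length")
  run <- function() {
    n_edits <- sample.int(max_edits + 1, 1) - 1
    s <- strsplit(seed_seq, "")[[1]]
    for (e in seq_len(n_edits)) {
      editable <- setdiff(2:(length(s) - 1),
                          if (is.null(protect)) integer(0) else protect[1]:protect[2])
      if (length(editable) == 0) break
      pos <- editable[sample.int(length(editable), 1)]
      op <- if (indels) sample(c("sub", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2)) else "sub"
      if (op == "sub") {
        s[pos] <- sample(setdiff(AA_ALPHABET, s[pos]), 1)
      } else if (op == "ins") {
        s <- append(s, sample(AA_ALPHABET, 1), after = pos)
        if (!is.null(protect) && pos < protect[1]) protect <- protect + 1
      } else {
        s <- s[-pos]
        if (!is.null(protect) && pos < protect[1]) protect <- protect - 1
      }
    }
    paste(s, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# unique sequences, topping up draws until n distinct ones avoid `avoid`
sample_unique_cdr3 <- function(n, length_mean, length_sd, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    draw <- sample_cdr3(n - length(out) + 10, length_mean, length_sd)
    out <- unique(c(out, setdiff(draw, avoid)))
  }
  out[seq_len(n)]
}

#' Generate the shared public pool and planted clusters
#'
#' Draws the public clonotype pools for both loci and, for each planted
#' cluster, a seed sequence with the cluster's motif inserted at a random
#' interior offset and member sequences mutated within `d_intra` edits of
#' the seed (edits never touch the motif span). The same pool can be passed
#' to several [generate_cohort()] calls (e.g. a discovery and a replication
#' cohort) so they share clusters.
#'
#' @param cfg a [synth_config()].
#' @return list with `pools` (per-locus character vectors), `clusters`
#'   (tibble: cluster_id, locus, junction_aa, motif), `motifs`.
#' @export
generate_public_pool <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, "pool"), {
    motifs <- cfg$motifs %||% (if (cfg$k_clusters > 0) {
      vapply(seq_len(cfg$k_clusters), function(k) {
        paste(sample(AA_ALPHABET, 4, replace = TRUE), collapse = "")
      }, character(1))
    } else character(0))
    if (cfg$k_clusters > 0 && length(motifs) != cfg$k_clusters) {
      abort("need one motif per planted cluster")
    }

    cluster_rows <- list()
    member_seqs <- list(IGH = character(0), TRB = character(0))
    for (k in seq_len(cfg$k_clusters)) {
      for (locus in LOCI) {
        sz <- if (locus == "IGH") cfg$cluster_size_b else cfg$cluster_size_t
        lm <- cfg$cdr3_length_mean[[locus]]
        repeat {
          seedseq <- sample_cdr3(1, lm, cfg$cdr3_length_sd)
          if (nchar(seedseq) >= nchar(motifs[k]) + 4) break
        }
        # plant the motif at a random interior offset of the seed
        off <- sample.int(nchar(seedseq) - nchar(motifs[k]) - 2, 1) + 1
        seedseq <- paste0(
          substr(seedseq, 1, off), motifs[k],
          substr(seedseq, off + nchar(motifs[k]) + 1, nchar(seedseq))
        )
        span <- c(off + 1, off + nchar(motifs[k]))
        members <- character(0)
        while (length(members) < sz) {
          cand <- mutate_within_ld(seedseq, cfg$d_intra, protect = span)
          if (!cand %in% c(members, unlist(member_seqs))) members <- c(members, cand)
        }
        member_seqs[[locus]] <- c(member_seqs[[locus]], members)
        cluster_rows[[length(cluster_rows) + 1]] <- tibble(
          cluster_id = k, locus = locus, junction_aa = members, motif = motifs[k]
        )
      }
    }
    clusters <- if (length(cluster_rows)) bind_rows(cluster_rows) else {
      tibble(cluster_id = integer(), locus = character(),
             junction_aa = character(), motif = character())
    }

    pools <- list()
    for (locus in LOCI) {
      extra <- cfg$public_size[[locus]] - length(member_seqs[[locus]])
      pools[[locus]] <- c(
        member_seqs[[locus]],
        sample_unique_cdr3(extra, cfg$cdr3_length_mean[[locus]],
                           cfg$cdr3_length_sd,
                           avoid = unlist(member_seqs))
      )
    }
    list(pools = pools, clusters = clusters, motifs = motifs)
  })
}

#' Generate a synthetic paired BCR/TCR cohort with ground truth
#'
#' Per individual `i`: a shared size latent `g_i` and diversity latent
#' `h_i` are drawn once; each chain's log clonal volume is
#' `mu_locus + sigma * (rho_size * g_i + sqrt(1 - rho_size^2) * eps)`, and
#' its Zipf tail exponent is `alpha * exp(alpha_mod * (rho_div * h_i +
#' sqrt(1 - rho_div^2) * eps))`. Non-cluster public clonotypes enter the
#' repertoire independently with probability `public_incl_prob`; members of
#' planted cluster `k` enter with probability
#' `plogis(qlogis(public_incl_prob) + presence_coupling * u_ik)` and, when
#' present, receive a weight proportional to
#' `softplus(lambda * u_ik + noise)`, where `u_ik ~ N(0, 1)` is the
#' per-individual cluster factor shared between the cluster's B and T
#' members. The remaining volume is filled with private sequences carrying
#' Zipf weights; counts are one guaranteed read per clonotype plus a
#' multinomial draw over the weights. Each individual has its own RNG
#' stream derived from (seed, study, individual), so generation is
#' reproducible independent of order.
#'
#' @param cfg a [synth_config()].
#' @param pool optional [generate_public_pool()] result to share clusters
#'   across cohorts; generated from `cfg` when NULL.
#' @param study_prefix prefix for study identifiers (default `"S"`).
#' @return list with `cohort` (a `cohort`), `ground_truth` (list:
#'   `individuals` tibble with g/h, `u` tibble with per-cluster factors,
#'   `clusters`, `motifs`), and `pool`.
#' @export
generate_cohort <- function(cfg, pool = NULL, study_prefix = "S") {
  pool <- pool %||% generate_public_pool(cfg)
  clusters <- pool$clusters
  cluster_members <- list(
    IGH = split(clusters$junction_aa[clusters$locus == "IGH"],
                clusters$cluster_id[clusters$locus == "IGH"]),
    TRB = split(clusters$junction_aa[clusters$locus == "TRB"],
                clusters$cluster_id[clusters$locus == "TRB"])
  )
  nonmember_pool <- list(
    IGH = setdiff(pool$pools$IGH, clusters$junction_aa),
    TRB = setdiff(pool$pools$TRB, clusters$junction_aa)
  )
  K <- cfg$k_clusters

  reps <- list(); gt_ind <- list(); gt_u <- list()
  for (s in seq_len(cfg$n_studies)) {
    study <- paste0(study_prefix, s)
    n_healthy <- round(cfg$healthy_fraction * cfg$individuals_per_study)
    for (i in seq_len(cfg$individuals_per_study)) {
      ind <- sprintf("I%02d", i)
      condition <- if (i <= n_healthy) "healthy" else "disease"
      stream <- derive_seed(cfg$seed, study, ind)
      res <- withr::with_seed(stream, {
        g <- rnorm(1); h <- rnorm(1)
        u <- if (K > 0) rnorm(K) else numeric(0)
        out <- list()
        for (locus in LOCI) {
          eps_s <- rnorm(1); eps_d <- rnorm(1)
          logn <- cfg$mu_log_size[[locus]] +
            cfg$sigma_log_size * (cfg$rho_size * g + sqrt(1 - cfg$rho_size^2) * eps_s)
          n_clono <- max(50L, as.integer(round(exp(logn))))
          a_i <- cfg$alpha * exp(cfg$alpha_mod *
            (cfg$rho_div * h + sqrt(1 - cfg$rho_div^2) * eps_d))

          # planted cluster members: presence and weight track u_ik
          memb_seqs <- character(0); memb_w <- numeric(0); memb_k <- integer(0)
          for (k in seq_len(K)) {
            mem <- cluster_members[[locus]][[as.character(k)]]
            p_in <- plogis(qlogis(cfg$public_incl_prob) +
                           cfg$presence_coupling * u[k])
            inc <- runif(length(mem)) < p_in
            if (any(inc)) {
              w <- softplus(cfg$lambda * u[k] +
                            rnorm(sum(inc), 0, cfg$cluster_noise_sd))
              memb_seqs <- c(memb_seqs, mem[inc])
              memb_w <- c(memb_w, w)
              memb_k <- c(memb_k, rep(k, sum(inc)))
            }
          }
          # other public clonotypes: flat inclusion probability
          pubs <- nonmember_pool[[locus]]
          pub_in <- pubs[runif(length(pubs)) < cfg$public_incl_prob]

          n_rest <- max(0L, n_clono - length(memb_seqs) - length(pub_in))
          priv <- sample_unique_cdr3(n_rest, cfg$cdr3_length_mean[[locus]],
                                     cfg$cdr3_length_sd,
                                     avoid = c(pool$pools$IGH, pool$pools$TRB))
          rest <- c(pub_in, priv)
          # Zipf weights over randomly assigned ranks for the non-cluster part
          ranks <- sample.int(length(rest))
          rest_w <- ranks^(-a_i)
          # scale cluster weights to the repertoire's typical clone weight
          memb_w <- memb_w * mean(rest_w)

          seqs <- c(memb_seqs, rest)
          w <- c(memb_w, rest_w)
          total_reads <- cfg$reads_per_clonotype * length(seqs)
          counts <- 1 + as.vector(rmultinom(1, total_reads - length(seqs), prob = w))

          subs <- if (cfg$assign_subsets) {
            opts <- CELL_SUBSETS[[locus]]
            memory <- grep("^memory", opts, value = TRUE)[1]
            lab <- sample(opts, length(seqs), replace = TRUE)
            if (length(memb_seqs)) lab[seq_along(memb_seqs)] <- memory
            lab
          } else NULL

          out[[locus]] <- repertoire(
            seqs, counts, locus, cell_subset = subs,
            individual_id = ind, study_id = study, condition = condition,
            quiet = TRUE
          )
        }
        list(reps = out, g = g, h = h, u = u)
      })
      reps[[length(reps) + 1]] <- res$reps$IGH
      reps[[length(reps) + 1]] <- res$reps$TRB
      gt_ind[[length(gt_ind) + 1]] <- tibble(
        study_id = study, individual_id = ind, condition = condition,
        g = res$g, h = res$h
      )
      if (K > 0) {
        gt_u[[length(gt_u) + 1]] <- tibble(
          study_id = study, individual_id = ind,
          cluster_id = seq_len(K), u = res$u
        )
      }
    }
  }

  list(
    cohort = cohort_from_repertoires(reps),
    ground_truth = list(
      individuals = bind_rows(gt_ind),
      u = if (K > 0) bind_rows(gt_u) else tibble(),
      clusters = clusters,
      motifs = pool$motifs
    ),
    pool = pool
  )
}

#' Write ground truth to a JSON file
#'
#' @param ground_truth the `ground_truth` element of [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(
      individuals = ground_truth$individuals,
      u = ground_truth$u,
      clusters = ground_truth$clusters,
      motifs = ground_truth$motifs
    ),
    path, dataframe = "columns", digits = NA
  )
  invisible(path)
}
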