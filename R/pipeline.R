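# End-to-end orchestration of the comparative study over multiple
# proteins x replicates: metrics -> statistics -> states -> clustering ->
# contacts -> segments, emitting a reproducible CSV/JSON report bundle.

#' Study configuration
#'
#' @param proteins named list; each entry a list with `trajectories`
#'   (list of `md_trajectory` replicates, equal count across proteins),
#'   `domain_map` (a [domain_map()]), optional `sequence` (protein
#'   sequence string) and optional `selections` (named list of residue
#'   vectors, merged with the map's own).
#' @param jaw_pair length-2 character vector naming the jaw domains used
#'   for open/close state analysis.
#' @param rule a [verdict_rule()].
#' @param cluster a [cluster_config()].
#' @param embed an [embed_config()].
#' @param interdomain_span EWMA span for interdomain distance series
#'   (1000 at the full 100,000-point scale; scaled by series length
#'   when shorter).
#' @param seed global seed recorded in the manifest.
#' @return an object of class `study_config`.
#' @export
study_config <- function(proteins, jaw_pair = c("PAZ", "MID"),
                         rule = verdict_rule(),
                         cluster = cluster_config(),
                         embed = embed_config(),
                         interdomain_span = 1000,
                         seed = 1L) {
  if (length(proteins) < 1 || is.null(names(proteins))) {
    stop_field("proteins", "must be a non-empty named list")
  }
  reps <- vapply(proteins, function(p) length(p$trajectories), integer(1))
  if (length(unique(reps)) != 1) {
    stop_field("proteins", "every protein needs the same replicate count")
  }
  structure(list(proteins = proteins, jaw_pair = jaw_pair, rule = rule,
                 cluster = cluster, embed = embed,
                 interdomain_span = interdomain_span,
                 seed = as.integer(seed)),
            class = "study_config")
}

# span for interdomain series: 1000 at 100k points, proportional below
interdomain_span_for <- function(config, n) {
  max(1L, as.integer(round(config$interdomain_span * min(1, n / 1e5))))
}

#' Run the full comparative study
#'
#' Produces, per protein: RMSD/RMSF/Rg tables, interdomain distance
#' summaries, clustering with medoids, open/closed state representatives
#' and contact catalogues; per protein pair: EWMA+KS verdicts on
#' whole-structure and per-domain RMSD per replicate, RMSF Frechet
#' distances on mapped residues (per named selection when sequences are
#' supplied), and jaw-distance time lags; plus the medoid 2D projection,
#' common-segment hits across supplied sequences, and a run manifest.
#' Any stage failure aborts with the stage name; completed outputs are
#' preserved under `out_dir/partial`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  results <- list()
  on.exit({
    if (!identical(stage, "done")) {
      part <- file.path(out_dir, "partial")
      dir.create(part, showWarnings = FALSE)
      writeLines(sprintf("aborted at stage: %s", stage),
                 file.path(part, "ABORTED.txt"))
    }
  })
  log_stage <- function(s) {
    stage <<- s
    message(sprintf("[pincerMD] stage: %s", s))
  }
  prots <- names(config$proteins)
  n_rep <- length(config$proteins[[1]]$trajectories)

  log_stage("metrics")
  metrics <- list()
  for (p in prots) {
    pm <- list()
    for (r in seq_len(n_rep)) {
      traj <- config$proteins[[p]]$trajectories[[r]]
      map <- config$proteins[[p]]$domain_map
      rmsd_whole <- rmsd_series(traj,
                                provenance = list(protein = p, replicate = r))
      rmsd_dom <- lapply(stats::setNames(map$entries$domain,
                                         map$entries$domain), function(d) {
        rmsd_series(traj, sel = domain_residues(map, d),
                    provenance = list(protein = p, replicate = r,
                                      selection = d))
      })
      pm[[r]] <- list(
        rmsd = rmsd_whole,
        rmsd_domain = rmsd_dom,
        rmsf = rmsf(traj, provenance = list(protein = p, replicate = r)),
        rg = radius_of_gyration(traj),
        interdomain = interdomain_distances(traj, map)
      )
      tab <- data.frame(frame = rmsd_whole$index,
                        rmsd_A = rmsd_whole$values,
                        rg_A = pm[[r]]$rg$values)
      write_table(tab, file.path(out_dir,
                                 sprintf("metrics_%s_R%d.csv", p, r)))
      write_table(as.data.frame(pm[[r]]$rmsf),
                  file.path(out_dir, sprintf("rmsf_%s_R%d.csv", p, r)))
      write_table(summary(pm[[r]]$interdomain),
                  file.path(out_dir,
                            sprintf("interdomain_summary_%s_R%d.csv", p, r)))
    }
    metrics[[p]] <- pm
  }
  results$metrics <- metrics

  log_stage("verdicts")
  verdict_rows <- list()
  if (length(prots) > 1) {
    pairs <- utils::combn(prots, 2)
    for (ci in seq_len(ncol(pairs))) {
      a <- pairs[1, ci]; b <- pairs[2, ci]
      doms_a <- config$proteins[[a]]$domain_map$entries$domain
      doms_b <- config$proteins[[b]]$domain_map$entries$domain
      targets <- c("whole", intersect(doms_a, doms_b))
      for (tg in targets) {
        recs <- lapply(seq_len(n_rep), function(r) {
          sa <- if (tg == "whole") metrics[[a]][[r]]$rmsd$values else
            metrics[[a]][[r]]$rmsd_domain[[tg]]$values
          sb <- if (tg == "whole") metrics[[b]][[r]]$rmsd$values else
            metrics[[b]][[r]]$rmsd_domain[[tg]]$values
          ks_compare(ewma(sa, default_span(length(sa))),
                     ewma(sb, default_span(length(sb))))
        })
        v <- replicate_verdict(recs, config$rule,
                               comparison = sprintf("%s|%s|%s", a, b, tg))
        write_verdict_json(v, file.path(out_dir,
                                        sprintf("verdict_%s_%s_%s.json",
                                                a, b, tg)))
        verdict_rows[[length(verdict_rows) + 1]] <-
          data.frame(protein_a = a, protein_b = b, target = tg,
                     outcome = v$outcome,
                     D_min = min(v$replicates$D),
                     p_max_observed = max(v$replicates$p))
      }
    }
    write_table(do.call(rbind, verdict_rows),
                file.path(out_dir, "verdict_grid.csv"))
  }
  results$verdicts <- verdict_rows

  log_stage("states")
  lag_rows <- list()
  if (length(prots) > 1) {
    pairs <- utils::combn(prots, 2)
    for (ci in seq_len(ncol(pairs))) {
      a <- pairs[1, ci]; b <- pairs[2, ci]
      for (r in seq_len(n_rep)) {
        ja <- pair_distance(metrics[[a]][[r]]$interdomain,
                            config$jaw_pair[1], config$jaw_pair[2])
        jb <- pair_distance(metrics[[b]][[r]]$interdomain,
                            config$jaw_pair[1], config$jaw_pair[2])
        span <- interdomain_span_for(config, length(ja))
        tl <- time_lag(smooth_normalize(ja, span),
                       smooth_normalize(jb, span))
        lag_rows[[length(lag_rows) + 1]] <-
          data.frame(protein_a = a, protein_b = b, replicate = r,
                     lag_frames = tl$lag, correlation = tl$correlation)
      }
    }
    write_table(do.call(rbind, lag_rows),
                file.path(out_dir, "time_lags.csv"))
  }
  results$time_lags <- lag_rows

  log_stage("clustering")
  clusterings <- list()
  medoid_jaw <- list()
  for (p in prots) {
    traj <- config$proteins[[p]]$trajectories[[1]]
    map <- config$proteins[[p]]$domain_map
    cl <- cluster_frames(traj, config$cluster)
    clusterings[[p]] <- cl
    write_table(data.frame(frame = seq_along(cl$labels),
                           cluster = cl$labels),
                file.path(out_dir, sprintf("clusters_%s.csv", p)))
    jaw <- pair_distance(metrics[[p]][[1]]$interdomain,
                         config$jaw_pair[1], config$jaw_pair[2])
    reps_ <- select_state_representatives(jaw[cl$medoids], cl$medoids)
    medoid_jaw[[p]] <- reps_
    write_topology_pdb(traj, file.path(out_dir,
                                       sprintf("state_open_%s.pdb", p)),
                       frame = reps_$open)
    write_topology_pdb(traj, file.path(out_dir,
                                       sprintf("state_closed_%s.pdb", p)),
                       frame = reps_$closed)
  }
  results$clusterings <- clusterings
  results$states <- medoid_jaw

  log_stage("contacts")
  catalogs <- list()
  for (p in prots) {
    traj <- config$proteins[[p]]$trajectories[[1]]
    medoids <- extract_medoids(clusterings[[p]], traj)
    cat_ <- unique_contact_catalog(medoids, traj$topology,
                                   map = config$proteins[[p]]$domain_map)
    catalogs[[p]] <- cat_
    write_table(cat_, file.path(out_dir, sprintf("contacts_%s.csv", p)))
  }
  results$contacts <- catalogs

  log_stage("segments")
  seqs <- lapply(config$proteins, function(p) p$sequence)
  seqs <- seqs[!vapply(seqs, is.null, logical(1))]
  if (length(seqs) >= 2) {
    hits <- longest_common_segments(unlist(seqs))
    write_table(segment_hits_table(hits),
                file.path(out_dir, "segments.csv"))
    results$segments <- hits

    log_stage("frechet")
    ref <- names(seqs)[1]
    frechet_rows <- list()
    others <- setdiff(names(seqs), ref)
    for (b in others) {
      mp <- map_residues(seqs[[ref]], seqs[[b]])
      for (r in seq_len(n_rep)) {
        fa <- metrics[[ref]][[r]]$rmsf
        fb <- metrics[[b]][[r]]$rmsf
        va <- fa$values[match(mp$pos_a, fa$index)]
        vb <- fb$values[match(mp$pos_b, fb$index)]
        keep <- !is.na(va) & !is.na(vb)
        frechet_rows[[length(frechet_rows) + 1]] <-
          data.frame(protein_a = ref, protein_b = b, replicate = r,
                     selection = "mapped",
                     frechet_A = frechet_distance(va[keep], vb[keep]))
      }
    }
    if (length(frechet_rows)) {
      write_table(do.call(rbind, frechet_rows),
                  file.path(out_dir, "frechet_rmsf.csv"))
      results$frechet <- do.call(rbind, frechet_rows)
    }
  }

  log_stage("projection")
  if (length(prots) > 1 && length(seqs) == length(prots)) {
    ref <- prots[1]
    mappings <- lapply(stats::setNames(setdiff(prots, ref),
                                       setdiff(prots, ref)), function(b) {
      map_residues(seqs[[ref]], seqs[[b]])
    })
    medoid_sets <- lapply(stats::setNames(prots, prots), function(p) {
      traj <- config$proteins[[p]]$trajectories[[1]]
      lapply(extract_medoids(clusterings[[p]], traj), function(f) {
        # rows indexed by residue number (one CA per residue)
        f[order(traj$topology$resno), , drop = FALSE]
      })
    })
    proj <- stack_and_project(medoid_sets, mappings, config$embed)
    write_table(proj, file.path(out_dir, "projection.csv"))
    results$projection <- proj
  }

  log_stage("manifest")
  manifest <- list(
    seed = config$seed,
    proteins = stats::setNames(lapply(prots, function(p) {
      list(replicates = n_rep,
           n_frames = n_frames(config$proteins[[p]]$trajectories[[1]]),
           n_atoms = n_atoms(config$proteins[[p]]$trajectories[[1]]))
    }), prots),
    jaw_pair = config$jaw_pair,
    rule = unclass(config$rule),
    cluster = unclass(config$cluster),
    embed = unclass(config$embed)[c("min_dist", "n_neighbours", "seed")],
    package_version = as.character(utils::packageVersion("pincerMD")),
    note = "no multiple-testing correction applied across the verdict grid"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- "done"
  invisible(results)
}
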