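# End-to-end orchestration: simulate (or load) -> trait scan -> eQTL ->
# causality filter -> cross network -> TIE ranking -> enrichment. One
# master seed governs every stochastic stage; rerunning the same
# configuration yields byte-identical outputs.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_tie_pipeline()].
#' With `stages$simulate = TRUE` (default) the pipeline generates a
#' synthetic study from `cross`; otherwise `inputs` must name existing
#' files (`genotypes`, `map`, `expression`, `trait`, `edges`,
#' `annotation`).
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage streams are derived from it.
#' @param cross a [cross_config()] (its own seed is overridden by `seed`).
#' @param stages named list of logical toggles: `simulate`, `scan`,
#'   `eqtl`, `causality`, `network`, `rank`, `enrich`.
#' @param alpha genome-wide significance level for the trait scan.
#' @param n_perm_threshold permutations for [genomewide_threshold()].
#' @param n_perm_tie permutations for [tie_score()].
#' @param lod_min eQTL peak cutoff; NULL reuses the trait's genome-wide
#'   threshold.
#' @param cis_window_bp cis window, base pairs.
#' @param lod_drop LOD-support interval fall-off.
#' @param min_degree TIE degree threshold.
#' @param inputs named list of file paths when not simulating; may also
#'   carry `terms` (a term annotation TSV with columns term_id, gene_id)
#'   for the enrichment stage.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, cross = cross_config(),
                            stages = list(), alpha = 0.05,
                            n_perm_threshold = 200, n_perm_tie = 200,
                            lod_min = NULL, cis_window_bp = 10000000,
                            lod_drop = 1.5, min_degree = 5,
                            inputs = list()) {
  default_stages <- list(simulate = TRUE, scan = TRUE, eqtl = TRUE,
                         causality = TRUE, network = TRUE, rank = TRUE,
                         enrich = TRUE)
  unknown <- setdiff(names(stages), names(default_stages))
  if (length(unknown)) stop2("unknown stage toggle(s): ", paste(unknown, collapse = ", "))
  default_stages[names(stages)] <- lapply(stages, isTRUE)
  if (is.list(cross) && !inherits(cross, "cross_config")) {
    cross <- do.call(cross_config, cross)
  }
  cross$seed <- seed
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cross = cross,
              stages = default_stages, alpha = alpha,
              n_perm_threshold = n_perm_threshold, n_perm_tie = n_perm_tie,
              lod_min = lod_min, cis_window_bp = cis_window_bp,
              lod_drop = lod_drop, min_degree = min_degree, inputs = inputs)
  if (!cfg$stages$simulate) {
    need <- c("genotypes", "map", "expression", "trait", "edges", "annotation")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop2("simulate disabled but inputs missing: ", paste(miss, collapse = ", "))
    }
    gone <- need[!file.exists(unlist(inputs[need]))]
    if (length(gone)) stop2("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full cross-loci pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' tab-delimited output (with a provenance metadata header: stage, seed,
#' parameters) under `out_dir`, and returns a manifest of the artifacts
#' produced. A stage failure aborts with the stage name; outputs of
#' earlier stages are retained. With the causality stage disabled, the
#' cross network is built from the unfiltered overlap gene sets and the
#' manifest notes the skip.
#'
#' @param config a [pipeline_config()], a plain list of its arguments, or
#'   the path to a YAML file holding them.
#' @return a `pipeline_manifest` data.frame: `stage`, `output`, `note`.
#' @export
run_tie_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  seeds <- derive_seeds(cfg$seed, 4)
  manifest <- list()
  note_row <- function(stage, output, note = "") {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, output = output, note = note, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
  }
  prov <- function(...) c(seed = as.character(cfg$seed), ...)

  ## stage 1: simulate or load
  study <- run_stage("simulate", function() {
    if (cfg$stages$simulate) {
      st <- simulate_f2_study(cfg$cross)
      write_genotypes(st$genotypes, pth("genotypes.tsv"), pth("map.tsv"))
      write_expression(st$expression, pth("expression.tsv"))
      write_trait(st$trait, pth("trait.tsv"))
      write_edges(st$ppi, pth("ppi_edges.tsv"))
      write_annotation(st$annotation, pth("annotation.tsv"))
      write_body(st$truth$roles, pth("truth_roles.tsv"), meta = prov())
      note_row("simulate", pth("genotypes.tsv"),
               sprintf("%d mice, %d markers, %d genes, %d PPI edges",
                       nrow(st$genotypes$codes), ncol(st$genotypes$codes),
                       nrow(st$expression), nrow(st$ppi)))
      st
    } else {
      st <- list(genotypes = read_genotypes(cfg$inputs$genotypes, cfg$inputs$map),
                 expression = read_expression(cfg$inputs$expression),
                 trait = read_trait(cfg$inputs$trait),
                 ppi = read_edges(cfg$inputs$edges),
                 annotation = read_annotation(cfg$inputs$annotation),
                 truth = NULL)
      note_row("simulate", cfg$inputs$genotypes, "loaded from disk (simulation disabled)")
      st
    }
  })

  ## stage 2: trait scan, threshold, intervals
  scan_res <- run_stage("scan", function() {
    thr <- genomewide_threshold(study$genotypes, study$trait,
                                n_perm = cfg$n_perm_threshold,
                                alpha = cfg$alpha, seed = seeds[1])
    curve <- scan_trait(study$genotypes, study$trait)
    intervals <- call_intervals(curve, thr, drop = cfg$lod_drop)
    write_body(as.data.frame(unclass(curve)), pth("trait_lod.tsv"),
               meta = prov(n_perm = cfg$n_perm_threshold,
                           alpha = cfg$alpha,
                           threshold = sprintf("%.4f", as.numeric(thr))))
    write_body(as.data.frame(unclass(intervals)), pth("trait_intervals.tsv"),
               meta = prov(lod_drop = cfg$lod_drop))
    note_row("scan", pth("trait_intervals.tsv"),
             sprintf("threshold %.2f, %d interval(s)", as.numeric(thr),
                     nrow(intervals)))
    list(threshold = as.numeric(thr), curve = curve, intervals = intervals)
  })
  if (nrow(scan_res$intervals) == 0) {
    warn2("no trait QTL intervals at the chosen threshold; downstream stages will be empty")
  }

  ## stage 3: eQTL scan, cis/trans, overlap
  calls <- run_stage("eqtl", function() {
    lod_min <- cfg$lod_min %||% scan_res$threshold
    cl <- scan_all_genes(study$genotypes, study$expression, lod_min = lod_min)
    cl <- classify_cis(cl, study$annotation, study$genotypes$map,
                       cis_window_bp = cfg$cis_window_bp)
    cl <- overlap_with_trait_qtl(cl, scan_res$intervals)
    write_body(cl, pth("eqtl_calls.tsv"),
               meta = prov(lod_min = sprintf("%.4f", lod_min),
                           cis_window_bp = cfg$cis_window_bp))
    n_ov <- length(unique(cl$gene_id[cl$overlapped_locus != "none"]))
    note_row("eqtl", pth("eqtl_calls.tsv"),
             sprintf("%d gene(s) with eQTL peaks; %d overlapping trait loci",
                     length(unique(cl$gene_id)), n_ov))
    cl
  })

  ## stage 4: causality filter
  sets <- run_stage("causality", function() {
    labels <- paste0("locus", seq_len(nrow(scan_res$intervals)))
    if (cfg$stages$causality) {
      cc <- classify_eqtl_genes(study$genotypes, study$expression,
                                study$trait, calls)
      write_body(cc, pth("causal_calls.tsv"), meta = prov())
      out <- filter_causal_reactive(cc)
      note_row("causality", pth("causal_calls.tsv"),
               sprintf("%d causal/reactive gene-locus pairs kept of %d tested",
                       sum(cc$label != "independent"), nrow(cc)))
      for (lb in setdiff(labels, names(out))) out[[lb]] <- character()
      out
    } else {
      out <- lapply(labels, function(lb) {
        sort(unique(calls$gene_id[calls$overlapped_locus %in% c(lb, "both")]))
      })
      names(out) <- labels
      write_body(data.frame(locus = rep(labels, lengths(out)),
                            gene_id = unlist(out, use.names = FALSE),
                            stringsAsFactors = FALSE),
                 pth("causal_calls.tsv"), meta = prov(causality = "disabled"))
      note_row("causality", pth("causal_calls.tsv"),
               "skipped (disabled): unfiltered overlap sets used")
      out
    }
  })

  ## stage 5: cross-group network
  net <- run_stage("network", function() {
    nw <- build_cross_network(study$ppi, sets[["locus1"]] %||% character(),
                              sets[["locus2"]] %||% character())
    write_cross_network(nw, pth("cross_network.sif"),
                        pth("cross_network_nodes.tsv"))
    fr <- cross_frequency(nw)
    note_row("network", pth("cross_network.sif"),
             sprintf("%d x %d genes, %d cross edges (%.2f%%)", fr$n_group1,
                     fr$n_group2, fr$n_edges,
                     ifelse(is.na(fr$frequency_pct), 0, fr$frequency_pct)))
    nw
  })

  ## stage 6: TIE ranking
  fit <- run_stage("rank", function() {
    ft <- tie_score(net, study$expression, study$trait,
                    min_degree = cfg$min_degree, n_perm = cfg$n_perm_tie,
                    seed = seeds[2])
    write_body(rank_table(ft), pth("tie_rank.tsv"),
               meta = prov(n_perm = cfg$n_perm_tie,
                           min_degree = cfg$min_degree))
    write_body(ft$edges, pth("edge_tipc.tsv"), meta = prov())
    note_row("rank", pth("tie_rank.tsv"),
             sprintf("%d gene(s) with non-zero TIE", sum(ft$records$tie > 0)))
    ft
  })

  ## stage 7: enrichment
  run_stage("enrich", function() {
    terms <- if (!is.null(cfg$inputs$terms)) {
      read_body(cfg$inputs$terms)
    } else if (!is.null(study$truth)) {
      data.frame(term_id = paste0("regulon_", study$truth$roles$regulator),
                 gene_id = study$truth$roles$gene_id, stringsAsFactors = FALSE)
    } else {
      NULL
    }
    query <- fit$records$gene_id[fit$records$tie > 0]
    if (is.null(terms) || !length(query)) {
      write_body(data.frame(term_id = character(), note = character()),
                 pth("enrichment.tsv"), meta = prov())
      note_row("enrich", pth("enrichment.tsv"),
               "skipped: no term annotation or empty query")
    } else {
      universe <- rownames(study$expression)
      enr <- hypergeom_enrich(query, terms, universe)
      write_body(enr, pth("enrichment.tsv"), meta = prov())
      note_row("enrich", pth("enrichment.tsv"),
               sprintf("%d term(s) tested on a %d-gene query", nrow(enr),
                       length(intersect(query, universe))))
    }
    NULL
  })

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  class(out) <- c("pipeline_manifest", "data.frame")
  out
}
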