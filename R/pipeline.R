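#' Run the full prediction pipeline from a YAML config
#'
#' Executes the stages data -> similarities -> heterogeneous network ->
#' RWR features -> autoencoder training -> cross-validation ->
#' prediction ranking, writing every stage artifact as labeled TSV into
#' the output directory together with a JSON manifest (parameters, seed,
#' and an md5 per artifact). A stage whose artifact already exists with
#' an unchanged parameter hash is skipped.
#'
#' Recognized config keys (all optional unless noted): `input`
#' (`associations` TSV path + optional `fasta`, or `synthetic` with any
#' [synthetic_spec()] field), `output_dir` (required), `seed`,
#' `embedding_dim`, `grid_size`, `restart_prob`, `features`,
#' `learning-rate`, `hidden1`, `hidden2`, `dropout`, `agg1`, `agg2`,
#' `epochs`, `negative_ratio`, `threshold`, `cv` (`k`, `policy`),
#' `top_k`.
#'
#' @param config_path path to the YAML configuration.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  cfg <- yaml::read_yaml(config_path)
  known <- c("input", "output_dir", "seed", "embedding_dim", "grid_size",
             "restart_prob", "features", "learning-rate", "hidden1",
             "hidden2", "dropout", "agg1", "agg2", "epochs",
             "negative_ratio", "threshold", "cv", "top_k",
             "mirna_weights", "stress_weights")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("config key 'output_dir' is required")
  if (is.null(cfg$input)) stop("config key 'input' is required")
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  say <- function(...) if (!quiet) message("[mirstress] ", ...)

  grab <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  enc <- encoder_config(
    hidden_dims = c(as.integer(grab("hidden1", 256L)),
                    as.integer(grab("hidden2", 128L))),
    aggregators = c(grab("agg1", "mean"), grab("agg2", "sum")),
    dropout = grab("dropout", 0), seed = seed)
  trn <- train_config(lr = grab("learning-rate", 0.001),
                      epochs = as.integer(grab("epochs", 200L)),
                      negative_ratio = grab("negative_ratio", 1),
                      seed = seed)
  pcfg <- pipeline_config(
    embedding_dim = as.integer(grab("embedding_dim", 100L)),
    grid_size = as.integer(grab("grid_size", 8L)),
    mirna_weights = unlist(grab("mirna_weights", c(1, 1, 1))),
    stress_weights = unlist(grab("stress_weights", c(1, 1))),
    restart_prob = grab("restart_prob", 0.7),
    features = grab("features", "rwr"),
    encoder = enc, train = trn,
    threshold = grab("threshold", 0.5), seed = seed)

  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(stages = list())
  manifest$package_version <- as.character(utils::packageVersion("mirstress"))
  manifest$seed <- seed

  param_hash <- function(params) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), f)
    unname(tools::md5sum(f))
  }
  cached <- function(stage, hash, files) {
    st <- manifest$stages[[stage]]
    !is.null(st) && identical(st$params, hash) &&
      all(file.exists(file.path(out, files)))
  }
  record <- function(stage, hash, files) {
    manifest$stages[[stage]] <<- list(
      params = hash, files = files,
      md5 = unname(tools::md5sum(file.path(out, files))))
  }

  # stage 1: dataset ------------------------------------------------------
  ds_hash <- param_hash(list(input = cfg$input, seed = seed))
  ds_file <- "association_matrix.tsv"
  if (!is.null(cfg$input$synthetic)) {
    spec_args <- cfg$input$synthetic
    spec_args$seed <- seed
    spec <- do.call(synthetic_spec, spec_args)
    gen <- generate_synthetic_dataset(spec)
    dataset <- gen$dataset
  } else {
    recs <- read_association_table(cfg$input$associations)
    seqs <- if (!is.null(cfg$input$fasta))
      read_fasta_sequences(cfg$input$fasta) else NULL
    dataset <- build_association_dataset(recs, seqs)
  }
  if (!cached("dataset", ds_hash, ds_file)) {
    write_matrix_tsv(dataset$A + 0, file.path(out, ds_file))
    record("dataset", ds_hash, ds_file)
    say("dataset: ", length(dataset$mirna_ids), " miRNAs x ",
        length(dataset$stress_terms), " stresses, ", sum(dataset$A),
        " associations")
  } else say("dataset: cached")

  # stage 2: stress-side similarities ------------------------------------
  sim_hash <- param_hash(list(ds = ds_hash, dim = pcfg$embedding_dim,
                              w = pcfg$stress_weights))
  s_files <- c("sim_sem.tsv", "sim_gipk_s.tsv", "sim_SS.tsv")
  emb <- train_stress_embeddings(dataset$stress_terms,
                                 dim = pcfg$embedding_dim, seed = seed)
  sem <- semantic_similarity(dataset, emb)
  gs <- gipk_matrix(t(dataset$A), "gipk_s")
  SS <- integrate_stress_similarity(sem, gs, weights = pcfg$stress_weights)
  if (!cached("stress_similarity", sim_hash, s_files)) {
    write_matrix_tsv(unclass(sem), file.path(out, s_files[1]))
    write_matrix_tsv(unclass(gs), file.path(out, s_files[2]))
    write_matrix_tsv(unclass(SS), file.path(out, s_files[3]))
    record("stress_similarity", sim_hash, s_files)
    say("stress similarities written")
  } else say("stress similarities: cached")

  # stage 3: miRNA-side similarities --------------------------------------
  msim_hash <- param_hash(list(ds = ds_hash, N = pcfg$grid_size,
                               w = pcfg$mirna_weights))
  m_files <- c("sim_seq.tsv", "sim_func.tsv", "sim_gipk_m.tsv", "sim_MS.tsv")
  seqsim <- sequence_similarity(dataset, grid_size = pcfg$grid_size)
  func <- functional_similarity(dataset, sem)
  gm <- gipk_matrix(dataset$A, "gipk_m")
  MS <- integrate_mirna_similarity(seqsim, func, gm,
                                   weights = pcfg$mirna_weights)
  if (!cached("mirna_similarity", msim_hash, m_files)) {
    write_matrix_tsv(unclass(seqsim), file.path(out, m_files[1]))
    write_matrix_tsv(unclass(func), file.path(out, m_files[2]))
    write_matrix_tsv(unclass(gm), file.path(out, m_files[3]))
    write_matrix_tsv(unclass(MS), file.path(out, m_files[4]))
    record("mirna_similarity", msim_hash, m_files)
    say("miRNA similarities written")
  } else say("miRNA similarities: cached")

  # stage 4: heterogeneous network ----------------------------------------
  net <- build_heterogeneous_network(MS, SS, dataset$A)
  h_hash <- param_hash(list(sim = c(sim_hash, msim_hash)))
  if (!cached("hetnet", h_hash, "hetnet_H.tsv")) {
    write_matrix_tsv(net$H, file.path(out, "hetnet_H.tsv"))
    record("hetnet", h_hash, "hetnet_H.tsv")
    say("heterogeneous network written (", net$clamped, " cells clamped)")
  } else say("hetnet: cached")

  # stage 5: RWR features --------------------------------------------------
  r_hash <- param_hash(list(h = h_hash, alpha = pcfg$restart_prob,
                            tol = pcfg$rwr_tol))
  rwr <- rwr_steady_state(net, restart_prob = pcfg$restart_prob,
                          tol = pcfg$rwr_tol,
                          max_iter = pcfg$rwr_max_iter)
  if (!cached("rwr", r_hash, "rwr_features.tsv")) {
    write_matrix_tsv(rwr$P, file.path(out, "rwr_features.tsv"))
    record("rwr", r_hash, "rwr_features.tsv")
    say("RWR features written (", rwr$iterations, " iterations)")
  } else say("rwr: cached")

  # stage 6: train on all known associations -------------------------------
  t_hash <- param_hash(list(r = r_hash, enc = unclass(enc),
                            trn = unclass(trn), feat = pcfg$features))
  m <- nrow(dataset$A); n <- ncol(dataset$A)
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  zero <- which(dataset$A == 0)
  old <- .Random.seed_save(); set.seed(seed)
  negs <- sample(zero, min(length(zero), ceiling(trn$negative_ratio * nrow(pos))))
  .Random.seed_restore(old)
  cells <- rbind(pos, cbind(((negs - 1L) %% m) + 1L, ((negs - 1L) %/% m) + 1L))
  yv <- c(rep(1, nrow(pos)), rep(0, length(negs)))
  X <- if (pcfg$features == "rwr") rwr$P else net$H
  model <- train_gae(X, net$H, cells, yv, m, n, config = enc, train = trn)
  if (!cached("train", t_hash, "score_matrix.tsv")) {
    write_matrix_tsv(model$scores, file.path(out, "score_matrix.tsv"))
    record("train", t_hash, "score_matrix.tsv")
    say("model trained; final loss ",
        format(utils::tail(model$loss_trace, 1), digits = 4))
  } else say("train: cached")

  # stage 7: cross-validation + prediction ranking -------------------------
  cv_k <- if (is.null(cfg$cv$k)) 5L else as.integer(cfg$cv$k)
  cv_policy <- if (is.null(cfg$cv$policy)) "strict" else cfg$cv$policy
  c_hash <- param_hash(list(t = t_hash, k = cv_k, policy = cv_policy,
                            top_k = grab("top_k", 10L)))
  c_files <- c("cv_metrics.tsv", "predictions.tsv")
  if (!cached("evaluate", c_hash, c_files)) {
    cv <- cross_validate(dataset, config = pcfg, k = cv_k,
                         policy = cv_policy, embeddings = emb)
    tab <- rbind(cv$per_fold,
                 data.frame(fold = NA, t(cv$mean)))
    utils::write.table(tab, file.path(out, c_files[1]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    preds <- rank_predictions(model$scores, dataset$A,
                              top_k = as.integer(grab("top_k", 10L)))
    utils::write.table(preds, file.path(out, c_files[2]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("evaluate", c_hash, c_files)
    say("cv mean AUPR ", sprintf("%.4f", cv$mean[["aupr"]]),
        ", AUC ", sprintf("%.4f", cv$mean[["auc"]]))
  } else say("evaluate: cached")

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifest_path)
  invisible(manifest)
}
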