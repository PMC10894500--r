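#' Tokenize stress terms
#'
#' @param terms character vector of (already normalized) stress terms.
#' @return list of character token vectors, one per term.
#' @keywords internal
tokenize_terms <- function(terms) {
  strsplit(normalize_stress_term(terms), " ", fixed = TRUE)
}

#' Train word embeddings on a corpus of stress terms
#'
#' Trains skip-gram embeddings with negative sampling (SGNS) on the
#' tokenized stress terms, treating each term as one short sentence.
#' Stress vocabularies are tiny (tens of tokens), so the plain-R training
#' loop is more than fast enough and fully deterministic for a fixed
#' seed. Negative samples are drawn from the unigram distribution raised
#' to the 3/4 power, the usual SGNS choice.
#'
#' @param stress_terms character vector of stress terms (the corpus).
#' @param dim embedding dimensionality (default 100).
#' @param seed integer RNG seed.
#' @param window symmetric context window in tokens (default 2).
#' @param epochs training passes over the corpus (default 80).
#' @param negative number of negative samples per context pair (default 5).
#' @param lr initial learning rate, linearly decayed (default 0.025).
#' @param min_count minimum token frequency to enter the vocabulary.
#' @return an `embedding_table`: list with `dim`, `vectors` (matrix, one
#'   row per vocabulary token), and `seed`.
#' @export
train_stress_embeddings <- function(stress_terms, dim = 100L, seed = 1L,
                                    window = 2L, epochs = 80L,
                                    negative = 5L, lr = 0.025,
                                    min_count = 1L) {
  stopifnot(dim >= 2L, epochs >= 1L)
  sentences <- tokenize_terms(stress_terms)
  tokens <- unlist(sentences)
  counts <- table(tokens)
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) < 2L) {
    stop("degenerate corpus: fewer than 2 distinct tokens; ",
         "supply an external embedding table instead")
  }
  vocab <- sort(vocab)
  V <- length(vocab)
  freq <- as.numeric(counts[vocab])
  neg_prob <- freq^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  sent_idx <- lapply(sentences, function(s) match(s[s %in% vocab], vocab))
  pairs <- do.call(rbind, lapply(sent_idx, function(ix) {
    n <- length(ix)
    if (n < 2L) return(NULL)
    out <- list()
    for (c in seq_len(n)) {
      ctx <- setdiff(max(1L, c - window):min(n, c + window), c)
      if (length(ctx)) out[[c]] <- cbind(ix[c], ix[ctx])
    }
    do.call(rbind, out)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("degenerate corpus: no (center, context) pairs within the window; ",
         "supply an external embedding table instead")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W_in <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
  W_out <- matrix(0, V, dim)

  n_steps <- epochs * nrow(pairs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (p in seq_len(nrow(pairs))) {
      step <- step + 1L
      alpha <- max(lr * (1 - step / n_steps), lr * 1e-4)
      cw <- pairs[p, 1L]; pos <- pairs[p, 2L]
      negs <- sample.int(V, negative, replace = TRUE, prob = neg_prob)
      targets <- c(pos, negs)
      labels <- c(1, rep(0, negative))
      v <- W_in[cw, ]
      u <- W_out[targets, , drop = FALSE]
      s <- 1 / (1 + exp(-(u %*% v)))
      g <- as.numeric(s) - labels            # d loss / d (u.v)
      W_out[targets, ] <- u - alpha * outer(g, v)
      W_in[cw, ] <- v - alpha * as.numeric(crossprod(u, g))
    }
  }
  rownames(W_in) <- vocab
  structure(list(dim = as.integer(dim), vectors = W_in, seed = seed),
            class = "embedding_table")
}

#' Load an external embedding table from TSV
#'
#' Expects rows of `token<TAB>x1<TAB>...<TAB>xd` with no header.
#'
#' @param path TSV path.
#' @return an `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  vecs <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vecs) <- as.character(df[[1L]])
  storage.mode(vecs) <- "double"
  structure(list(dim = ncol(vecs), vectors = vecs, seed = NA_integer_),
            class = "embedding_table")
}

#' Vector representation of a stress term
#'
#' Multi-token terms are represented by the element-wise mean of their
#' token vectors; tokens missing from the vocabulary are skipped with a
#' warning.
#'
#' @param term a single stress term.
#' @param table an `embedding_table`.
#' @return numeric vector of length `table$dim`.
#' @export
stress_vector <- function(term, table) {
  stopifnot(inherits(table, "embedding_table"))
  toks <- tokenize_terms(term)[[1L]]
  known <- toks[toks %in% rownames(table$vectors)]
  unknown <- setdiff(toks, known)
  if (length(unknown)) {
    warning("unknown token(s) in '", term, "': ",
            paste(unknown, collapse = ", "))
  }
  if (length(known) == 0L) {
    stop("term '", term, "' has no token in the embedding vocabulary")
  }
  colMeans(table$vectors[known, , drop = FALSE])
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
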