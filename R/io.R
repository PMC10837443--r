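# Tabular I/O, cross-dataset normalization and clinical imputation.

#' Read a gene x sample expression matrix
#'
#' Expects delimited text with a header row of sample identifiers and gene
#' identifiers in the first column. Values must be numeric (log2 scale by
#' convention). Gzip-compressed files are read transparently.
#'
#' @param path File path (TSV by default).
#' @param delim Field delimiter.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene column and at least ",
                         "one sample column", call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate sample identifiers: ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (any(!is.finite(m))) stop("non-finite expression values present",
                               call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Expects columns `sample_id`, `time_days` (or `time`), `event` (0/1) and
#' optionally `age`, `fab` (M0-M7 or 0-7), `eln2017`
#' (Favorable/Intermediate/Adverse). Missing clinical cells are kept as `NA`.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return List with `outcome` (tibble `sample_id`, `time`, `event`) and
#'   `clinical` (tibble `sample_id`, `age`, `fab`, `eln2017`).
#' @export
read_clinical <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  tcol <- intersect(c("time_days", "time"), names(df))[1]
  need <- c("sample_id", "event")
  miss <- setdiff(need, names(df))
  if (is.na(tcol) || length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(c(if (is.na(tcol)) "time_days", miss), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  time <- as.numeric(df[[tcol]])
  event <- df$event
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad)) {
    stop("event must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    stop("times must be positive; offending row(s): ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  }
  fab_levels <- paste0("M", 0:7)
  fab <- if ("fab" %in% names(df)) {
    f <- as.character(df$fab)
    f[f %in% as.character(0:7)] <- paste0("M", f[f %in% as.character(0:7)])
    bad_f <- !is.na(f) & !(f %in% fab_levels)
    if (any(bad_f)) stop("fab values outside M0-M7: ",
                         paste(unique(f[bad_f]), collapse = ", "),
                         call. = FALSE)
    factor(f, levels = fab_levels)
  } else factor(rep(NA_character_, nrow(df)), levels = fab_levels)
  eln_levels <- c("Favorable", "Intermediate", "Adverse")
  eln <- if ("eln2017" %in% names(df)) {
    e <- as.character(df$eln2017)
    bad_e <- !is.na(e) & !(e %in% eln_levels)
    if (any(bad_e)) stop("eln2017 values outside the declared domain: ",
                         paste(unique(e[bad_e]), collapse = ", "),
                         call. = FALSE)
    factor(e, levels = eln_levels)
  } else factor(rep(NA_character_, nrow(df)), levels = eln_levels)
  list(
    outcome = tibble::tibble(sample_id = ids, time = time,
                             event = as.integer(event)),
    clinical = tibble::tibble(
      sample_id = ids,
      age = if ("age" %in% names(df)) as.numeric(df$age) else NA_real_,
      fab = fab, eln2017 = eln
    )
  )
}

#' Read / write a gene signature coefficient file
#'
#' Two-column delimited text: `gene`, `coefficient`.
#' @param path File path.
#' @param delim Field delimiter.
#' @param provenance Free-text provenance attached to the signature.
#' @return A [gene_signature].
#' @export
read_signature <- function(path, delim = "\t", provenance = path) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) stop("signature file needs gene and coefficient columns",
                         call. = FALSE)
  gene_signature(as.character(df[[1]]), as.numeric(df[[2]]),
                 provenance = provenance)
}

#' @rdname read_signature
#' @param signature A [gene_signature].
#' @export
write_signature <- function(signature, path) {
  readr::write_tsv(tibble::tibble(gene = signature$genes,
                                  coefficient = signature$betas), path)
  invisible(path)
}

#' Harmonize expression distributions across datasets
#'
#' Restricts all matrices to their common gene set (intersection, preserving
#' the first matrix's gene order), concatenates the samples, and equalizes
#' per-sample distributions by full quantile normalization
#' (via [limma::normalizeBetweenArrays]).
#'
#' @param matrices A single expression matrix or a list of them.
#' @param method Normalization method passed to limma (default
#'   `"quantile"`).
#' @return A list of normalized matrices in the input order (a list even for
#'   a single input).
#' @export
normalize_between_datasets <- function(matrices, method = "quantile") {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0) {
    stop("no genes shared across the supplied datasets", call. = FALSE)
  }
  genes <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% genes]
  cut <- lapply(matrices, function(m) m[genes, , drop = FALSE])
  combined <- do.call(cbind, cut)
  norm <- limma::normalizeBetweenArrays(combined, method = method)
  sizes <- vapply(cut, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- lapply(seq_along(cut), function(i) {
    m <- norm[, starts[i]:ends[i], drop = FALSE]
    dimnames(m) <- dimnames(cut[[i]])
    m
  })
  names(out) <- names(matrices)
  out
}

#' Impute missing clinical covariates by iterative random forests
#'
#' missForest-style round-robin imputation: each incomplete column is
#' regressed (numeric) or classified (factor) on all other columns with a
#' random forest, missing cells are replaced by predictions, and the cycle
#' repeats until the imputed values change by less than `tol` (normalized
#' RMSE for numerics, disagreement fraction for factors) or `max_iter`
#' passes. Observed cells are never altered.
#'
#' @param table Data frame with a `sample_id` column and clinical columns;
#'   `NA` marks missing cells.
#' @param rng_seed Integer seed (forests are randomized).
#' @param max_iter,tol Stopping rule.
#' @param ntree Trees per forest.
#' @return The completed table (same shape, observed values untouched).
#' @export
impute_clinical <- function(table, rng_seed = 1L, max_iter = 10, tol = 1e-3,
                            ntree = 100) {
  stopifnot(is.data.frame(table))
  id_col <- intersect("sample_id", names(table))
  work <- as.data.frame(table[, setdiff(names(table), id_col),
                              drop = FALSE])
  for (j in names(work)) {
    if (is.character(work[[j]])) work[[j]] <- factor(work[[j]])
  }
  miss <- vapply(work, function(col) sum(is.na(col)), integer(1))
  if (all(miss == 0)) return(table)
  fully <- names(miss)[miss == nrow(work)]
  if (length(fully)) {
    stop("column(s) fully missing, cannot impute: ",
         paste(fully, collapse = ", "), call. = FALSE)
  }
  na_idx <- lapply(work, function(col) which(is.na(col)))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(rng_seed)

  # initialize with column mean / modal category
  for (j in names(work)) {
    idx <- na_idx[[j]]
    if (!length(idx)) next
    if (is.numeric(work[[j]])) {
      work[[j]][idx] <- mean(work[[j]], na.rm = TRUE)
    } else {
      tab <- table(work[[j]])
      work[[j]][idx] <- names(tab)[which.max(tab)]
    }
  }

  cols <- names(miss)[miss > 0]
  cols <- cols[order(miss[cols])]            # least-missing first
  for (iter in seq_len(max_iter)) {
    change <- 0
    for (j in cols) {
      idx <- na_idx[[j]]
      obs <- setdiff(seq_len(nrow(work)), idx)
      preds <- work[, setdiff(names(work), j), drop = FALSE]
      if (ncol(preds) == 0) next
      fit <- randomForest::randomForest(x = preds[obs, , drop = FALSE],
                                        y = work[[j]][obs], ntree = ntree)
      new_vals <- stats::predict(fit, preds[idx, , drop = FALSE])
      old_vals <- work[[j]][idx]
      if (is.numeric(work[[j]])) {
        denom <- stats::sd(work[[j]][obs])
        if (!is.finite(denom) || denom == 0) denom <- 1
        change <- max(change, sqrt(mean((as.numeric(new_vals) -
                                           as.numeric(old_vals))^2)) / denom)
        work[[j]][idx] <- as.numeric(new_vals)
      } else {
        change <- max(change, mean(as.character(new_vals) !=
                                     as.character(old_vals)))
        work[[j]][idx] <- as.character(new_vals)
      }
    }
    if (change < tol) break
  }
  out <- table
  for (j in names(work)) {
    idx <- na_idx[[j]]
    if (!length(idx)) next
    if (is.factor(out[[j]])) {
      out[[j]][idx] <- factor(as.character(work[[j]][idx]),
                              levels = levels(out[[j]]))
    } else {
      out[[j]][idx] <- work[[j]][idx]
    }
  }
  out
}

# Align an expression matrix's samples with an outcome/clinical table.
align_samples <- function(expr, outcome) {
  oc <- as_outcome(outcome)
  if (is.null(oc$sample_id) || is.null(colnames(expr))) {
    if (ncol(expr) != length(oc$time)) {
      stop("expression and outcome sample counts differ", call. = FALSE)
    }
    return(list(expr = expr, time = oc$time, event = oc$event))
  }
  common <- intersect(colnames(expr), oc$sample_id)
  if (length(common) == 0) stop("no shared samples between expression and ",
                                "outcome", call. = FALSE)
  keep <- match(common, oc$sample_id)
  list(expr = expr[, common, drop = FALSE],
       time = oc$time[keep], event = oc$event[keep], sample_id = common)
}
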