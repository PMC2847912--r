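new_contrast_set <- function(K, m, row_labels, group_labels) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == length(m), nrow(K) == length(row_labels),
            ncol(K) == length(group_labels))
  if (any(rowSums(abs(K)) == 0)) stop("contrast matrix has an all-zero row")
  if (anyDuplicated(row_labels)) stop("duplicate contrast labels")
  dimnames(K) <- list(row_labels, group_labels)
  structure(list(matrix = K, rhs = as.numeric(m),
                 row_labels = row_labels, group_labels = group_labels),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Contrast set:", nrow(x$matrix), "contrasts on",
      length(x$group_labels), "groups\n")
  print(cbind(x$matrix, rhs = x$rhs))
  invisible(x)
}

#' @method tidy contrast_set
#' @export
tidy.contrast_set <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "contrast") |>
    dplyr::mutate(rhs = x$rhs)
}

#' Tukey all-pairwise contrasts
#'
#' One row per unordered pair of groups, coded `later - earlier` in label
#' order (+1 on the later label, -1 on the earlier), right-hand side 0.
#' For `p` groups this yields `p(p-1)/2` contrasts.
#'
#' @param group_labels Ordered character vector of group labels (e.g.
#'   `fit$group_labels`).
#' @return A `contrast_set`.
#' @examples
#' contrast_tukey(c("A", "B", "C"))
#' @export
contrast_tukey <- function(group_labels) {
  p <- length(group_labels)
  if (p < 2L) stop("need >= 2 groups for pairwise contrasts")
  pairs <- utils::combn(p, 2L)
  k <- ncol(pairs)
  K <- matrix(0, k, p)
  labs <- character(k)
  for (r in seq_len(k)) {
    i <- pairs[1L, r]; j <- pairs[2L, r]      # i < j in label order
    K[r, j] <- 1; K[r, i] <- -1
    labs[r] <- paste(group_labels[j], "-", group_labels[i])
  }
  # combn order: for each earlier label, all later ones (the usual listing)
  new_contrast_set(K, rep(0, k), labs, group_labels)
}

#' Dunnett many-to-one contrasts
#'
#' One row per non-reference group, coded `other - reference`, right-hand
#' side 0. Non-reference rows keep the ingest order of the labels.
#'
#' @inheritParams contrast_tukey
#' @param reference Label of the control group; defaults to the first label.
#' @return A `contrast_set`.
#' @export
contrast_dunnett <- function(group_labels, reference = group_labels[1L]) {
  p <- length(group_labels)
  if (p < 2L) stop("need >= 2 groups")
  ref <- match(reference, group_labels)
  if (is.na(ref)) {
    stop("unknown reference \"", reference, "\"; valid labels: ",
         paste(group_labels, collapse = ", "))
  }
  others <- setdiff(seq_len(p), ref)
  K <- matrix(0, length(others), p)
  labs <- character(length(others))
  for (r in seq_along(others)) {
    K[r, others[r]] <- 1; K[r, ref] <- -1
    labs[r] <- paste(group_labels[others[r]], "-", group_labels[ref])
  }
  new_contrast_set(K, rep(0, length(others)), labs, group_labels)
}

#' Parse symbolic contrast expressions
#'
#' Turns strings like `"PE4 - PE3 = 0"` or `"A + 0.5*B - 1.5*C = 1"` into
#' contrast rows over the given group labels. Each expression must name
#' every group at most once; groups not named get coefficient 0; the value
#' after `=` becomes the right-hand side (0 if `=` is omitted).
#'
#' @param expressions Character vector, one expression per contrast.
#' @inheritParams contrast_tukey
#' @return A `contrast_set`.
#' @examples
#' contrast_parse("PE4 - PE3 = 0", c("PE3", "PE4", "PE5"))
#' @export
contrast_parse <- function(expressions, group_labels) {
  stopifnot(is.character(expressions), length(expressions) >= 1L)
  rows <- lapply(expressions, parse_one_contrast, group_labels = group_labels)
  K <- do.call(rbind, lapply(rows, `[[`, "coef"))
  m <- vapply(rows, `[[`, numeric(1), "rhs")
  labs <- vapply(rows, `[[`, character(1), "label")
  new_contrast_set(K, m, labs, group_labels)
}

parse_one_contrast <- function(expr, group_labels) {
  parts <- strsplit(expr, "=", fixed = TRUE)[[1L]]
  if (length(parts) > 2L) {
    stop("malformed contrast \"", expr, "\": more than one '='")
  }
  lhs <- trimws(parts[1L])
  rhs <- if (length(parts) == 2L) {
    v <- suppressWarnings(as.numeric(trimws(parts[2L])))
    if (is.na(v)) stop("malformed contrast \"", expr,
                       "\": right-hand side is not a number")
    v
  } else 0
  if (nchar(lhs) == 0L) stop("malformed contrast \"", expr, "\": empty left side")

  # split into signed terms: coefficient ('*' optional) followed by a label
  term_re <- "([+-]?)\\s*(\\d+\\.?\\d*|\\.\\d+)?\\s*\\*?\\s*([[:alnum:]_.]+)"
  stripped <- gsub("\\s", "", lhs)
  coefs <- stats::setNames(numeric(length(group_labels)), group_labels)
  seen <- character(0)
  pos <- 1L
  while (pos <= nchar(stripped)) {
    m <- regexpr(paste0("^", term_re), substr(stripped, pos, nchar(stripped)))
    if (m == -1L) {
      stop("malformed contrast \"", expr, "\": parse error at position ", pos)
    }
    frag <- regmatches(substr(stripped, pos, nchar(stripped)), m)
    g <- regmatches(frag, regexec(paste0("^", term_re), frag))[[1L]]
    sign <- if (identical(g[2L], "-")) -1 else 1
    coef <- if (nzchar(g[3L])) as.numeric(g[3L]) else 1
    label <- g[4L]
    if (!label %in% group_labels) {
      stop("unknown label \"", label, "\" in contrast \"", expr,
           "\" (position ", pos, "); valid labels: ",
           paste(group_labels, collapse = ", "))
    }
    if (label %in% seen) {
      stop("duplicate label \"", label, "\" in contrast \"", expr, "\"")
    }
    seen <- c(seen, label)
    coefs[label] <- sign * coef
    pos <- pos + attr(m, "match.length")
  }
  list(coef = coefs, rhs = rhs, label = trimws(lhs))
}

#' Resolve a contrast specification against a set of group labels
#'
#' Accepts `"tukey"`, `"dunnett"`, `"dunnett:<ref>"`, a character vector of
#' symbolic expressions, or an existing `contrast_set` (checked for matching
#' labels).
#'
#' @param spec Contrast specification (see Details).
#' @inheritParams contrast_tukey
#' @return A `contrast_set`.
#' @export
resolve_contrasts <- function(spec, group_labels) {
  if (inherits(spec, "contrast_set")) {
    if (!identical(spec$group_labels, group_labels)) {
      stop("contrast set was built for different group labels")
    }
    return(spec)
  }
  stopifnot(is.character(spec))
  if (length(spec) == 1L) {
    low <- tolower(spec)
    if (low == "tukey") return(contrast_tukey(group_labels))
    if (low == "dunnett") return(contrast_dunnett(group_labels))
    if (startsWith(low, "dunnett:")) {
      return(contrast_dunnett(group_labels,
                              reference = sub("^[Dd]unnett:", "", spec)))
    }
  }
  contrast_parse(spec, group_labels)
}
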