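#' Treatment ontologies
#'
#' An ontology groups the treatment vocabulary `A` into therapeutic classes
#' (the map `alpha(a)`, e.g. ATC-style groupings), optionally lists similarity
#' edges between treatments, and carries a symmetric affinity kernel
#' `K(a_i, a_j)` in `[0, 1]` with `K(a, a) = 1`. Kernel entries not given
#' explicitly default to 1 for same-class pairs and 0 across classes, the
#' minimal class-co-membership knowledge source.
#'
#' @param class_of named character vector mapping treatment id to class label.
#' @param similarity_edges optional 2-column matrix / data frame of unordered
#'   treatment pairs.
#' @param kernel optional explicit kernel entries: a 3-column data frame
#'   `(i, j, value)` or a full named square matrix. Entries are symmetrised;
#'   conflicting asymmetric values are an error.
#' @return a `td_ontology` list with `vocabulary`, `class_of`, `classes`,
#'   `similarity_edges` and the completed `kernel` matrix.
#' @export
ontology <- function(class_of, similarity_edges = NULL, kernel = NULL) {
  if (is.null(names(class_of)) || any(!nzchar(names(class_of))))
    stop("class_of must be a named character vector (treatment id -> class)")
  vocab <- names(class_of)
  if (anyDuplicated(vocab)) stop("duplicated treatment ids in class_of")
  classes <- sort(unique(unname(class_of)))
  n <- length(vocab)

  K <- outer(unname(class_of), unname(class_of), "==") * 1
  dimnames(K) <- list(vocab, vocab)
  if (!is.null(kernel)) {
    ent <- kernel_entries(kernel, vocab)
    given <- matrix(FALSE, n, n, dimnames = dimnames(K))
    for (r in seq_len(nrow(ent))) {
      i <- ent$i[r]; j <- ent$j[r]; v <- ent$value[r]
      if (!i %in% vocab || !j %in% vocab)
        stop("validation error: kernel entry references unknown id: ", i, ", ", j)
      if (v < 0 || v > 1)
        stop("validation error: kernel value ", v, " outside [0, 1]")
      if (i == j && v != 1)
        stop("validation error: kernel(a, a) must equal 1")
      if (given[j, i] && K[j, i] != v)
        stop("validation error: asymmetric explicit kernel entries for (",
             i, ", ", j, ")")
      K[i, j] <- v; K[j, i] <- v
      given[i, j] <- TRUE; given[j, i] <- TRUE
    }
  }

  edges <- normalize_edges(similarity_edges, vocab)
  structure(list(vocabulary = vocab,
                 class_of = class_of,
                 classes = classes,
                 similarity_edges = edges,
                 kernel = K),
            class = "td_ontology")
}

kernel_entries <- function(kernel, vocab) {
  if (is.matrix(kernel) && nrow(kernel) == ncol(kernel) && !is.null(rownames(kernel))) {
    idx <- expand.grid(i = rownames(kernel), j = colnames(kernel),
                       stringsAsFactors = FALSE)
    idx$value <- as.numeric(kernel)
    return(idx)
  }
  df <- as.data.frame(kernel, stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("kernel must be a named square matrix or (i, j, value) triples")
  names(df) <- c("i", "j", "value")
  df$i <- as.character(df$i); df$j <- as.character(df$j)
  df$value <- as.numeric(df$value)
  df
}

normalize_edges <- function(edges, vocab) {
  if (is.null(edges) || (is.data.frame(edges) && !nrow(edges)) ||
      (is.matrix(edges) && !nrow(edges)) || (is.list(edges) && !length(edges))) {
    return(matrix(character(0), ncol = 2L))
  }
  em <- if (is.data.frame(edges)) as.matrix(edges) else
    if (is.list(edges) && !is.matrix(edges)) do.call(rbind, edges) else edges
  em <- matrix(as.character(em), ncol = 2L)
  bad <- setdiff(unique(as.vector(em)), vocab)
  if (length(bad)) stop("validation error: similarity edge references unknown id: ",
                        paste(bad, collapse = ", "))
  if (any(em[, 1] == em[, 2])) stop("validation error: self-loop similarity edge")
  # canonical unordered form, deduplicated
  em <- t(apply(em, 1L, sort))
  em <- em[!duplicated(paste(em[, 1], em[, 2])), , drop = FALSE]
  unname(em)
}

#' Read a treatment ontology from JSON
#'
#' Schema:
#' `{"classes": {id: class, ...}, "similarity_edges": [[id, id], ...],
#'   "kernel": [[id, id, value], ...]}`
#' (`similarity_edges` and `kernel` optional).
#'
#' @param path file path.
#' @return a `td_ontology`.
#' @export
read_ontology <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$classes) || !length(obj$classes))
    stop("parse error: ontology file has no 'classes' map")
  class_of <- vapply(obj$classes, as.character, "")
  edges <- if (length(obj$similarity_edges))
    do.call(rbind, lapply(obj$similarity_edges, function(e) c(e[[1]], e[[2]])))
  kern <- if (length(obj$kernel))
    data.frame(i = vapply(obj$kernel, function(e) as.character(e[[1]]), ""),
               j = vapply(obj$kernel, function(e) as.character(e[[2]]), ""),
               value = vapply(obj$kernel, function(e) as.numeric(e[[3]]), 0))
  ontology(class_of, similarity_edges = edges, kernel = kern)
}

#' Write a treatment ontology to JSON
#'
#' Emits the full completed kernel so a round trip reproduces the object.
#' @param ontology a `td_ontology`.
#' @param path output file.
#' @export
write_ontology <- function(ontology, path) {
  v <- ontology$vocabulary
  kern <- list()
  for (i in seq_along(v)) for (j in i:length(v))
    kern[[length(kern) + 1L]] <- list(v[i], v[j], ontology$kernel[v[i], v[j]])
  obj <- list(classes = as.list(ontology$class_of),
              similarity_edges = apply(ontology$similarity_edges, 1L, as.list,
                                       simplify = FALSE),
              kernel = kern)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))), path)
  invisible(path)
}

# edge list as parsed from JSON: either already a 2-column matrix
# (simplified) or a list of pairs
edges_from_json <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  if (is.matrix(x)) x else do.call(rbind, lapply(x, function(e) c(e[[1]], e[[2]])))
}

# integer codes used by the numerical core
treatment_index <- function(a, ontology) {
  idx <- match(a, ontology$vocabulary)
  if (anyNA(idx)) stop("unknown treatment id(s): ",
                       paste(unique(a[is.na(idx)]), collapse = ", "))
  idx
}

class_index <- function(a, ontology) {
  match(ontology$class_of[a], ontology$classes)
}

# all unordered intra-class pairs (indices into vocabulary), i < j
intra_class_pairs <- function(ontology) {
  v <- ontology$vocabulary
  out <- NULL
  for (cl in ontology$classes) {
    members <- which(unname(ontology$class_of[v]) == cl)
    if (length(members) >= 2L) {
      cmb <- utils::combn(members, 2L)
      out <- cbind(out, cmb)
    }
  }
  if (is.null(out)) matrix(integer(0), nrow = 2L) else out
}
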