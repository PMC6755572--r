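#' Fingerprint configuration
#'
#' Bundles the choices that determine a binary molecular fingerprint:
#' the backend kind, the folded length and (for circular fingerprints)
#' the neighborhood radius.
#'
#' Backends:
#' \describe{
#'   \item{`morgan`}{circular (ECFP-like) substructure fingerprint computed
#'     from the molecular graph by iterative neighborhood hashing, folded
#'     to `n_bits`; `radius` controls the largest neighborhood.}
#'   \item{`path`}{path-based hashed fingerprint (Daylight-like; OpenBabel
#'     FP2), folded to `n_bits`.}
#'   \item{`maccs`}{the fixed MACCS structural key set; `n_bits` and
#'     `radius` are ignored.}
#' }
#' Fingerprinting is deterministic: the same structure under the same
#' configuration always yields the same bits.
#'
#' @param kind one of `"morgan"`, `"path"`, `"maccs"`.
#' @param n_bits folded length in bits (>= 64); default 1024, beyond about
#'   1000 bits folding has negligible influence on Tanimoto similarities.
#' @param radius circular-neighborhood radius for `morgan` (default 2).
#' @return object of class `fp_config`.
#' @export
fp_config <- function(kind = c("morgan", "path", "maccs"),
                      n_bits = 1024L, radius = 2L) {
  kind <- match.arg(kind)
  n_bits <- as.integer(n_bits)
  radius <- as.integer(radius)
  if (kind != "maccs" && n_bits < 64L)
    stop_gknn("n_bits must be >= 64 for folded fingerprints",
              class = "gknn_value_error")
  if (radius < 0L)
    stop_gknn("radius must be >= 0", class = "gknn_value_error")
  structure(list(kind = kind, n_bits = n_bits, radius = radius),
            class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  cat(sprintf("fingerprint config: %s (%d bits%s)\n", x$kind, x$n_bits,
              if (x$kind == "morgan") paste0(", radius ", x$radius) else ""))
  invisible(x)
}

# Parse one SMILES into a ChemmineR SDF object; NULL when unparsable.
parse_smiles <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  mol <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1]]),
    error = function(e) NULL)
  if (is.null(mol)) return(NULL)
  ab <- tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  mol
}

# 31-bit deterministic polynomial hash; exact in double arithmetic.
hash_ints <- function(ints) {
  h <- 7
  for (v in ints) h <- (h * 31 + v) %% 2147483647
  h
}

element_number <- function(symbol) {
  idx <- match(symbol, c("H", "He", "Li", "Be", "B", "C", "N", "O", "F",
                         "Ne", "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
                         "K", "Ca", "Fe", "Cu", "Zn", "Br", "I"))
  ifelse(is.na(idx), 90 + (utf8ToInt(substr(symbol, 1, 1)) %% 30), idx)
}

# Circular (Morgan/ECFP-style) fingerprint from the connectivity table.
# Atom invariants seed from (element, heavy degree, bond-order sum, charge);
# each iteration rehashes an atom with its sorted (bond order, neighbor
# invariant) pairs, and every (atom, iteration) invariant sets one folded bit.
morgan_bits <- function(mol, n_bits, radius) {
  ab <- ChemmineR::atomblock(mol)
  n_atoms <- nrow(ab)
  symbols <- sub("_\\d+$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  nb <- vector("list", n_atoms)
  border <- vector("list", n_atoms)
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    for (r in seq_len(nrow(bb))) {
      a <- bb[r, 1]; b <- bb[r, 2]; o <- bb[r, 3]
      if (a < 1 || b < 1 || a > n_atoms || b > n_atoms) next
      nb[[a]] <- c(nb[[a]], b); border[[a]] <- c(border[[a]], o)
      nb[[b]] <- c(nb[[b]], a); border[[b]] <- c(border[[b]], o)
    }
  }
  charge <- if (ncol(ab) >= 6) ab[, 6] else rep(0, n_atoms)
  inv <- vapply(seq_len(n_atoms), function(i) {
    hash_ints(c(element_number(symbols[i]), length(nb[[i]]),
                sum(border[[i]]), charge[i]))
  }, numeric(1))
  bits <- inv %% n_bits
  if (radius > 0) {
    for (it in seq_len(radius)) {
      inv <- vapply(seq_len(n_atoms), function(i) {
        if (length(nb[[i]]) == 0) return(hash_ints(c(inv[i], it)))
        ord <- order(border[[i]], inv[nb[[i]]])
        hash_ints(c(inv[i],
                    as.vector(rbind(border[[i]][ord], inv[nb[[i]]][ord]))))
      }, numeric(1))
      bits <- c(bits, inv %% n_bits)
    }
  }
  sort(unique(as.integer(bits))) + 1L  # 1-based bit positions
}

ob_bits <- function(mols_sdf, kind) {
  fpname <- if (kind == "maccs") "MACCS" else "FP2"
  fp <- ChemmineR::fingerprintOB(mols_sdf, fpname)
  methods::slot(fp, "fpma") > 0
}

#' Compute binary fingerprints for a set of structures
#'
#' @param smiles character vector of SMILES strings.
#' @param config an [fp_config()].
#' @param ids optional identifiers used for row names and error messages.
#' @return logical matrix, one row per structure, `n_bits` columns, with
#'   attributes `kind`, `n_bits`, `radius`; class `fingerprints`.
#' @export
fingerprints <- function(smiles, config = fp_config(), ids = NULL) {
  ids <- ids %||% as.character(seq_along(smiles))
  mols <- lapply(smiles, parse_smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad))
    stop_gknn("unparsable SMILES for: ",
              paste(sprintf("%s ('%s')", ids[bad], smiles[bad]),
                    collapse = ", "),
              class = "gknn_parse_error")
  if (config$kind == "morgan") {
    m <- matrix(FALSE, length(smiles), config$n_bits)
    for (i in seq_along(mols))
      m[i, morgan_bits(mols[[i]], config$n_bits, config$radius)] <- TRUE
  } else {
    sdfset <- methods::new("SDFset", SDF = mols, ID = ids)
    m <- ob_bits(sdfset, config$kind)
    dimnames(m) <- NULL
  }
  rownames(m) <- ids
  structure(m, kind = config$kind, n_bits = ncol(m),
            radius = config$radius, class = c("fingerprints", "matrix"))
}

#' @export
`[.fingerprints` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod("[")
  if (is.matrix(out) && ncol(out) == ncol(unclass(x)))
    structure(out, kind = attr(x, "kind"), n_bits = attr(x, "n_bits"),
              radius = attr(x, "radius"), class = class(x))
  else out
}

fp_compatible <- function(a, b) {
  identical(attr(a, "kind"), attr(b, "kind")) &&
    identical(ncol(a), ncol(b))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits. Two all-zero fingerprints are
#' defined as identical (similarity 1); an all-zero against a nonzero
#' fingerprint scores 0.
#'
#' @param a,b logical bit vectors (rows of a [fingerprints()] matrix) of
#'   the same kind and length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop_gknn("fingerprints have incompatible lengths",
              class = "gknn_incompatible_error")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes the full query-by-reference Tanimoto matrix, either from two
#' datasets (fingerprinting their structures under `config`) or directly
#' from two [fingerprints()] matrices.
#'
#' @param query,reference dataset data.frames with `chem_id` and `smiles`
#'   columns, or `fingerprints` matrices. `reference = NULL` reuses
#'   `query` (self-similarity matrix: symmetric with unit diagonal).
#' @param config an [fp_config()] (ignored when fingerprints are passed).
#' @return numeric matrix in `[0, 1]` with `chem_id` dimnames; class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(query, reference = NULL, config = fp_config()) {
  as_fp <- function(x) {
    if (inherits(x, "fingerprints")) return(x)
    validate_dataset(x, endpoint = NULL, require_structure = TRUE)
    fingerprints(x$smiles, config, ids = x$chem_id)
  }
  fq <- as_fp(query)
  fr <- if (is.null(reference)) fq else as_fp(reference)
  if (!fp_compatible(fq, fr))
    stop_gknn("query and reference fingerprints are incompatible",
              class = "gknn_incompatible_error")
  A <- matrix(as.numeric(fq), nrow(fq), ncol(fq))
  B <- matrix(as.numeric(fr), nrow(fr), ncol(fr))
  common <- tcrossprod(A, B)
  union <- outer(rowSums(A), rowSums(B), `+`) - common
  s <- ifelse(union == 0, 1, common / pmax(union, 1))
  dimnames(s) <- list(rownames(fq), rownames(fr))
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity matrix: %d query x %d reference chemicals\n",
              nrow(x), ncol(x)))
  cat(sprintf("  range [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

#' Read/write a similarity matrix as CSV with identifier headers
#'
#' @param sm similarity matrix.
#' @param path CSV file path.
#' @return `write_similarity()` returns `path` invisibly;
#'   `read_similarity()` returns a `similarity_matrix`.
#' @export
write_similarity <- function(sm, path) {
  df <- data.frame(chem_id = rownames(sm), as.data.frame(unclass(sm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  structure(m, class = c("similarity_matrix", "matrix"))
}
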