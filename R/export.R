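#' Export a decision tree as if-else source code
#'
#' Unrolls a trained tree into a self-contained C function of nested
#' if-else statements over a feature array, the standard deployment form
#' for constant-overhead inference on embedded targets. Thresholds are
#' printed with `%.17g`, which round-trips IEEE doubles exactly: rounding
#' them would move decision boundaries and can flip classifications for
#' feature values computed on a different platform.
#'
#' The returned object carries both the source text and a structural view
#' parsed back *from that text*, so that parity between the exported code
#' and the in-memory model can be checked by an interpreter that never saw
#' the original tree (see [predict_exported()]).
#'
#' @param model A `patchfreq_tree`.
#' @param function_name Name of the emitted function.
#' @return An object of class `patchfreq_tree_code`: list with `code`
#'   (single string), `function_name`, `n_nodes`, and `structure` (the
#'   node tree re-parsed from the emitted text).
#' @export
#' @examples
#' tbl <- tibble::tibble(label = c(0L, 1L), f1 = c(0, 1))
#' code <- export_if_else(train_tree(tbl), "classify")
#' cat(code$code)
export_if_else <- function(model, function_name = "predict_patch") {
  if (!inherits(model, "patchfreq_tree")) {
    abort("export_if_else() needs a patchfreq_tree.",
      class = "patchfreq_bad_model"
    )
  }
  nodes <- model$nodes
  emit <- function(id, indent) {
    pad <- strrep("    ", indent)
    if (nodes$is_leaf[id]) {
      return(paste0(pad, "return ", nodes$class[id], ";"))
    }
    c(
      paste0(
        pad, "if (features[", nodes$feature[id], "] <= ",
        sprintf("%.17g", nodes$threshold[id]), ") {"
      ),
      emit(nodes$left[id], indent + 1L),
      paste0(pad, "} else {"),
      emit(nodes$right[id], indent + 1L),
      paste0(pad, "}")
    )
  }
  lines <- c(
    paste0("int ", function_name, "(const double *features) {"),
    emit(model$root, 1L),
    "}"
  )
  code <- paste(lines, collapse = "\n")
  structure(
    list(
      code = code, function_name = function_name,
      n_nodes = nrow(nodes), structure = parse_if_else(code)
    ),
    class = "patchfreq_tree_code"
  )
}

# Recursive-descent parser for the emitted if-else dialect. Works on the
# text alone; used as the independent side of export-parity checks.
parse_if_else <- function(code) {
  lines <- trimws(strsplit(code, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  if (!grepl("^int [A-Za-z_][A-Za-z0-9_]* *\\(const double \\*features\\) \\{$",
    lines[1]
  )) {
    abort("Not an exported if-else tree.", class = "patchfreq_bad_code")
  }
  pos <- 2L
  parse_block <- function() {
    line <- lines[pos]
    if (grepl("^return [01];$", line)) {
      pos <<- pos + 1L
      return(list(leaf = TRUE, class = as.integer(sub("^return ([01]);$", "\\1", line))))
    }
    m <- regmatches(
      line,
      regexec("^if \\(features\\[([0-9]+)\\] <= ([^)]+)\\) \\{$", line)
    )[[1]]
    if (length(m) != 3L) {
      abort(paste0("Unparseable line: ", line), class = "patchfreq_bad_code")
    }
    pos <<- pos + 1L
    left <- parse_block()
    if (!identical(lines[pos], "} else {")) {
      abort("Malformed else branch.", class = "patchfreq_bad_code")
    }
    pos <<- pos + 1L
    right <- parse_block()
    if (!identical(lines[pos], "}")) {
      abort("Unbalanced braces.", class = "patchfreq_bad_code")
    }
    pos <<- pos + 1L
    list(
      leaf = FALSE, feature = as.integer(m[2]),
      threshold = as.numeric(m[3]), left = left, right = right
    )
  }
  out <- parse_block()
  if (!identical(lines[pos], "}")) {
    abort("Unbalanced function body.", class = "patchfreq_bad_code")
  }
  out
}

#' Execute exported if-else code on feature vectors
#'
#' Structural interpreter for the text produced by [export_if_else()]: the
#' decision logic is reconstructed from the source alone and executed,
#' providing an independent check that the exported code reproduces the
#' in-memory model's predictions.
#'
#' @param code A `patchfreq_tree_code` object or the exported source text.
#' @param newdata Numeric matrix or vector of feature values (columns in
#'   the training order the code indexes into).
#' @return Integer vector of 0/1 predictions.
#' @export
predict_exported <- function(code, newdata) {
  node <- if (inherits(code, "patchfreq_tree_code")) {
    code$structure
  } else {
    parse_if_else(code)
  }
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  one <- function(xrow) {
    nd <- node
    while (!nd$leaf) {
      nd <- if (xrow[nd$feature + 1L] <= nd$threshold) nd$left else nd$right
    }
    nd$class
  }
  vapply(seq_len(nrow(newdata)), function(i) one(newdata[i, ]), integer(1))
}

#' @export
print.patchfreq_tree_code <- function(x, ...) {
  cat(x$code, "\n")
  invisible(x)
}
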