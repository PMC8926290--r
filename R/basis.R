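# Gaussian basis-set tables and shell-list construction for the C++ kernels.

basis_cache <- new.env(parent = emptyenv())

#' Load a Gaussian basis-set table
#'
#' Reads one of the plain-text basis tables shipped with the package
#' (`sto-3g`, `6-31g`, `cc-pvdz`).  Coefficients refer to normalized
#' primitives; normalization is applied inside the integral kernels.
#'
#' @param name basis-set name (case-insensitive).
#' @return a named list: per element, a list of shells with fields `l`
#'   (0/1 angular momentum, `"SP"` shells are expanded), `exps`, `coefs`.
#' @export
load_basis <- function(name) {
  key <- tolower(name)
  if (!is.null(basis_cache[[key]])) return(basis_cache[[key]])
  path <- system.file("extdata", "basis", paste0(key, ".txt"),
                      package = "saptvqe")
  if (!nzchar(path)) stop("unknown basis set: ", name)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); el <- NULL; shell <- NULL
  flush_shell <- function() {
    if (is.null(shell)) return()
    if (shell$type == "SP") {
      out[[el]][[length(out[[el]]) + 1L]] <<-
        list(l = 0L, exps = shell$exps, coefs = shell$c1)
      out[[el]][[length(out[[el]]) + 1L]] <<-
        list(l = 1L, exps = shell$exps, coefs = shell$c2)
    } else {
      l <- match(shell$type, c("S", "P", "D")) - 1L
      out[[el]][[length(out[[el]]) + 1L]] <<-
        list(l = l, exps = shell$exps, coefs = shell$c1)
    }
    shell <<- NULL
  }
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      flush_shell()
      el <- canonical_element(tok[2])
      out[[el]] <- list()
    } else if (tok[1] == "shell") {
      flush_shell()
      shell <- list(type = toupper(tok[2]), exps = numeric(0),
                    c1 = numeric(0), c2 = numeric(0))
    } else {
      v <- as.numeric(tok)
      shell$exps <- c(shell$exps, v[1])
      shell$c1 <- c(shell$c1, v[2])
      if (shell$type == "SP") shell$c2 <- c(shell$c2, v[3])
    }
  }
  flush_shell()
  basis_cache[[key]] <- out
  out
}

# Flat shell list for a molecule, in the layout the C++ kernels expect.
# Coordinates already in bohr.
shell_list <- function(mol, basis_name) {
  tab <- load_basis(basis_name)
  missing <- setdiff(unique(mol$elements), names(tab))
  if (length(missing))
    stop(sprintf("basis '%s' has no entry for element(s): %s", basis_name,
                 paste(missing, collapse = ", ")))
  l <- integer(0); x <- y <- z <- numeric(0)
  nprim <- integer(0); pstart <- integer(0)
  pexp <- pcoef <- numeric(0)
  for (i in seq_along(mol$elements)) {
    for (sh in tab[[mol$elements[i]]]) {
      l <- c(l, sh$l)
      x <- c(x, mol$coords[i, 1]); y <- c(y, mol$coords[i, 2])
      z <- c(z, mol$coords[i, 3])
      pstart <- c(pstart, length(pexp))
      nprim <- c(nprim, length(sh$exps))
      pexp <- c(pexp, sh$exps); pcoef <- c(pcoef, sh$coefs)
    }
  }
  list(l = l, x = x, y = y, z = z, nprim = nprim, pstart = pstart,
       pexp = pexp, pcoef = pcoef,
       nbf = as.integer(sum((l + 1L) * (l + 2L)) %/% 2L))
}

# concatenate two shell lists (dimer basis)
shell_concat <- function(s1, s2) {
  list(l = c(s1$l, s2$l), x = c(s1$x, s2$x), y = c(s1$y, s2$y),
       z = c(s1$z, s2$z), nprim = c(s1$nprim, s2$nprim),
       pstart = c(s1$pstart, s2$pstart + length(s1$pexp)),
       pexp = c(s1$pexp, s2$pexp), pcoef = c(s1$pcoef, s2$pcoef),
       nbf = s1$nbf + s2$nbf)
}
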