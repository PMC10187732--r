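#' Generate an H/P heteropolymer sequence
#'
#' Draws a two-letter sequence of length `N` with exactly `round(N * X_P)`
#' polar (P) monomers; composition is a controlled variable, so the count is
#' enforced exactly rather than drawn Bernoulli-wise (ties such as
#' `N * X_P = 2.5` follow round-half-to-even). By default P positions are
#' sampled without replacement; `patterned = TRUE` instead spaces the P
#' monomers maximally uniformly along the chain, emulating highly patterned
#' sequence sets.
#'
#' @param N chain length (monomers), `>= 2`.
#' @param X_P fraction of polar monomers, in `[0, 1]`.
#' @param seed integer seed for reproducible placement (`NULL` uses the
#'   current RNG stream).
#' @param patterned place P monomers evenly instead of randomly.
#' @param label optional record label; defaults to `"XP<value>"`.
#' @return A one-row [tibble::tibble] with columns `label`, `N`, `X_P`
#'   (nominal), `n_P`, `seed`, `patterned`, `sequence`.
#' @examples
#' generate_sequence(20, 0.25, seed = 7)
#' @export
generate_sequence <- function(N, X_P, seed = NULL, patterned = FALSE,
                              label = NULL) {
  if (!is.numeric(X_P) || length(X_P) != 1 || X_P < 0 || X_P > 1)
    abort("`X_P` must be a single fraction in [0, 1].")
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N != round(N))
    abort("`N` must be an integer >= 2.")
  n_P <- as.integer(round(N * X_P))
  mono <- rep("H", N)
  if (n_P == N) {
    mono[] <- "P"
  } else if (n_P > 0) {
    pos <- if (patterned) {
      floor((seq_len(n_P) - 0.5) * N / n_P) + 1L
    } else {
      with_seed(seed, sample.int(N, n_P))
    }
    mono[pos] <- "P"
  }
  if (is.null(label)) label <- sprintf("XP%.2f", X_P)
  tibble(label = label, N = as.integer(N), X_P = X_P, n_P = n_P,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         patterned = patterned, sequence = paste(mono, collapse = ""))
}

#' Sequence set over a composition grid
#'
#' One random sequence per grid point `X_P = 0, step, ..., 1`; the default
#' `step = 0.05` with `N = 20` yields the 21-sequence design the downstream
#' pipeline sweeps.
#'
#' @param N chain length.
#' @param step grid spacing; must divide 1 evenly.
#' @param seed base seed; each grid point gets a distinct derived sub-seed.
#' @param patterned passed through to [generate_sequence()].
#' @return A tibble with one row per sequence.
#' @export
sequence_grid <- function(N = 20, step = 0.05, seed = 1, patterned = FALSE) {
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) abort("`step` must divide 1 evenly.")
  xs <- seq(0, 1, by = step)
  purrr::map_dfr(seq_along(xs), function(i) {
    generate_sequence(N, xs[i], seed = derive_seed(seed, paste0("seq", i)),
                      patterned = patterned)
  })
}

#' Read and write H/P sequence sets as FASTA
#'
#' Plain FASTA with sequence lines over the `{H, P}` alphabet. Headers carry
#' the label plus `X_P=` and `seed=` fields, which round-trip through
#' `write_sequences()` / `read_sequences()`.
#'
#' @param seqs a sequence tibble ([generate_sequence()] rows).
#' @param path file path.
#' @return `read_sequences()` returns a sequence tibble (zero rows for an
#'   empty file); `write_sequences()` returns `path` invisibly.
#' @export
write_sequences <- function(seqs, path) {
  lines <- unlist(purrr::pmap(seqs, function(label, X_P, seed, patterned,
                                             sequence, ...) {
    hdr <- sprintf(">%s X_P=%s seed=%s patterned=%s", label,
                   format(X_P), ifelse(is.na(seed), "NA", seed),
                   ifelse(isTRUE(patterned), "TRUE", "FALSE"))
    c(hdr, sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(label = character(), N = integer(), X_P = double(),
                  n_P = integer(), seed = integer(), patterned = logical(),
                  sequence = character()))
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0 || starts[1] != 1)
    abort("not a FASTA file: no '>' header on the first line.")
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map_dfr(seq_along(starts), function(k) {
    hdr <- sub("^>", "", lines[starts[k]])
    body <- paste(lines[(starts[k] + 1L):ends[k]], collapse = "")
    body <- gsub("\\s", "", body)
    bad <- setdiff(unique(strsplit(body, "")[[1]]), c("H", "P"))
    if (length(bad) > 0)
      abort(sprintf("record '%s' contains illegal characters: %s",
                    strsplit(hdr, " ")[[1]][1], paste(bad, collapse = ", ")))
    label <- strsplit(hdr, " ")[[1]][1]
    get_field <- function(name, default = NA) {
      m <- regmatches(hdr, regexpr(paste0(name, "=\\S+"), hdr))
      if (length(m) == 0) return(default)
      sub(paste0(name, "="), "", m)
    }
    xp <- suppressWarnings(as.numeric(get_field("X_P")))
    sd_ <- suppressWarnings(as.integer(get_field("seed")))
    pat <- identical(get_field("patterned", "FALSE"), "TRUE")
    n_P <- sum(strsplit(body, "")[[1]] == "P")
    if (is.na(xp)) xp <- n_P / nchar(body)
    tibble(label = label, N = nchar(body), X_P = xp, n_P = as.integer(n_P),
           seed = sd_, patterned = pat, sequence = body)
  })
}

# character vector of monomer letters for one sequence row
monomers_of <- function(seq_row) {
  strsplit(seq_row$sequence[[1]], "")[[1]]
}
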