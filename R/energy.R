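# Nearest-neighbour energy backends and single-sequence loop energies.

BP_SET <- c("AU", "UA", "GC", "CG", "GU", "UG")

is_valid_pair <- function(x, y) paste0(x, y) %in% BP_SET

#' Toy nearest-neighbour energy backend
#'
#' A deliberately simple parameter set in which every energy is
#' hand-computable: each stack of two valid pairs contributes -2.0 kcal/mol,
#' closing a hairpin costs +3.0, a bulge or internal loop +2.0, closing a
#' multiloop +4.0, and the external loop contributes 0. Intended for tests
#' and worked examples; use [turner_backend()] for realistic energies.
#'
#' @return An object of class `energy_backend`.
#' @export
toy_backend <- function() {
  structure(list(
    name = "toy",
    hairpin = function(seq, i, j) 3.0,
    stack = function(seq, i, j) {
      ci <- substr(seq, i, i); cj <- substr(seq, j, j)
      ck <- substr(seq, i + 1L, i + 1L); cl <- substr(seq, j - 1L, j - 1L)
      if (!is_valid_pair(ci, cj) || !is_valid_pair(ck, cl))
        stop("invalid base pair queried as a stack: (", i, ",", j, ") on ",
             "(", i + 1L, ",", j - 1L, ")")
      -2.0
    },
    bulge = function(seq, i, j, k, l) 2.0,
    internal = function(seq, i, j, k, l) 2.0,
    multiloop = function(seq, i, j, branches, unpaired) 4.0,
    external = function(seq, branches) 0.0
  ), class = "energy_backend")
}

#' Turner-style nearest-neighbour energy backend
#'
#' Loads a simplified Turner-style parameter table (37 degrees C, kcal/mol)
#' from a plain-text file: a 6x6 stacking table over
#' `{AU, UA, GC, CG, GU, UG}`, loop-length initiation energies for hairpin,
#' bulge and internal loops with Jacobson-Stockmayer logarithmic
#' extrapolation beyond the tabulated lengths, and an affine multiloop score.
#' Dangling ends, coaxial stacking, terminal AU penalties and sequence-specific
#' loop bonuses are excluded so the loop decomposition stays unambiguous.
#'
#' @param path Parameter file; defaults to the table bundled with the package.
#' @return An object of class `energy_backend`.
#' @export
turner_backend <- function(path = system.file("extdata", "nn_params.txt",
                                              package = "rnalikin")) {
  par <- read_nn_params(path)
  loop_energy <- function(table, n) {
    n <- max(n, 1L)
    if (n <= length(table) && !is.na(table[n])) return(table[n])
    nmax <- max(which(!is.na(table)))
    # Jacobson-Stockmayer entropic extrapolation at 37 C (1.75 RT)
    table[nmax] + 1.75 * 0.0019872 * 310.15 * log(n / nmax)
  }
  structure(list(
    name = "turner",
    hairpin = function(seq, i, j) loop_energy(par$hairpin, j - i - 1L),
    stack = function(seq, i, j) {
      p1 <- paste0(substr(seq, i, i), substr(seq, j, j))
      p2 <- paste0(substr(seq, i + 1L, i + 1L), substr(seq, j - 1L, j - 1L))
      if (!(p1 %in% BP_SET) || !(p2 %in% BP_SET))
        stop("invalid base pair queried as a stack: ", p1, "/", p2)
      par$stack[p1, p2]
    },
    bulge = function(seq, i, j, k, l) {
      n <- (k - i - 1L) + (j - l - 1L)
      loop_energy(par$bulge, n)
    },
    internal = function(seq, i, j, k, l) {
      n <- (k - i - 1L) + (j - l - 1L)
      loop_energy(par$internal, n)
    },
    multiloop = function(seq, i, j, branches, unpaired) {
      par$ml_closing + par$ml_branch * (branches + 1L) + par$ml_unpaired * unpaired
    },
    external = function(seq, branches) 0.0
  ), class = "energy_backend")
}

read_nn_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(BP_SET, BP_SET))
  hairpin <- rep(NA_real_, 30L)
  bulge <- rep(NA_real_, 30L)
  internal <- rep(NA_real_, 30L)
  ml <- c(closing = NA_real_, branch = NA_real_, unpaired = NA_real_)
  for (f in fields) {
    key <- f[1]
    if (key == "stack") {
      stack[f[2], f[3]] <- as.numeric(f[4])
    } else if (key %in% c("hairpin", "bulge", "internal")) {
      n <- as.integer(f[2])
      v <- as.numeric(f[3])
      if (key == "hairpin") hairpin[n] <- v
      else if (key == "bulge") bulge[n] <- v
      else internal[n] <- v
    } else if (key == "multiloop") {
      ml[f[2]] <- as.numeric(f[3])
    } else {
      stop("unknown parameter key: ", key)
    }
  }
  if (anyNA(stack)) stop("incomplete stacking table in ", path)
  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       ml_closing = ml[["closing"]], ml_branch = ml[["branch"]],
       ml_unpaired = ml[["unpaired"]])
}

# Loop decomposition: for each pair, its direct children (pairs immediately
# nested inside with no intervening pair), and the top-level (external) pairs.
loop_tree <- function(pairs) {
  n <- nrow(pairs)
  if (!n) return(list(children = list(), top = integer(0)))
  parent <- rep(0L, n)  # 0 = external loop
  for (a in seq_len(n)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    enc <- which(pairs[, 1L] < i & pairs[, 2L] > j)
    if (length(enc)) {
      # tightest enclosing pair
      parent[a] <- enc[which.max(pairs[enc, 1L])]
    }
  }
  children <- lapply(seq_len(n), function(a) which(parent == a))
  list(children = children, top = which(parent == 0L))
}

#' Free energy of a structure on a single sequence
#'
#' Sums loop energies over the unique loop decomposition of `s`: hairpin,
#' stack, bulge, internal and multiloop contributions as defined by the
#' backend; the external loop contributes via the backend's external term
#' (zero for both provided backends).
#'
#' @param seq Ungapped sequence (string over ACGU).
#' @param s An [rna_structure()] with `s$length == nchar(seq)`.
#' @param backend An energy backend, e.g. [toy_backend()].
#' @return Energy in kcal/mol.
#' @examples
#' sequence_energy("GGGAAACCC", parse_dotbracket("(((...)))"), toy_backend())
#' @export
sequence_energy <- function(seq, s, backend) {
  stopifnot(inherits(s, "rna_structure"), inherits(backend, "energy_backend"))
  seq <- toupper(gsub("T", "U", seq, fixed = TRUE))
  if (nchar(seq) != s$length)
    stop("sequence length ", nchar(seq), " does not match structure length ",
         s$length)
  pairs <- s$pairs
  if (!nrow(pairs)) return(backend$external(seq, 0L))
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- is_valid_pair(sc[pairs[, 1L]], sc[pairs[, 2L]])
  if (!all(ok)) {
    a <- which(!ok)[1]
    stop("invalid base pair for this sequence: (", pairs[a, 1L], ",",
         pairs[a, 2L], ") = ", sc[pairs[a, 1L]], "-", sc[pairs[a, 2L]])
  }
  tree <- loop_tree(pairs)
  e <- backend$external(seq, length(tree$top))
  for (a in seq_len(nrow(pairs))) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    kids <- tree$children[[a]]
    if (!length(kids)) {
      e <- e + backend$hairpin(seq, i, j)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1L]; l <- pairs[kids, 2L]
      if (k == i + 1L && l == j - 1L) {
        e <- e + backend$stack(seq, i, j)
      } else if (k == i + 1L || l == j - 1L) {
        e <- e + backend$bulge(seq, i, j, k, l)
      } else {
        e <- e + backend$internal(seq, i, j, k, l)
      }
    } else {
      unpaired <- (j - i - 1L) -
        sum(pairs[kids, 2L] - pairs[kids, 1L] + 1L)
      e <- e + backend$multiloop(seq, i, j, length(kids), unpaired)
    }
  }
  e
}
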