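#' The six cladogenetic model variants
#'
#' @return Character vector of canonical model names.
#' @export
biogeo_models <- function() {
  c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J", "BAYAREALIKE", "BAYAREALIKE+J")
}

#' Parse a model name into family and founder flag
#'
#' Accepts the canonical names of [biogeo_models()] and common spellings
#' such as `"DECj"` or `"decJ"`.
#'
#' @param model Model name.
#' @return List with `family` (`"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`),
#'   `founder` (logical) and `name` (canonical form).
#' @export
model_spec <- function(model) {
  m <- toupper(gsub("[+*]", "", model))
  founder <- grepl("J$", m)
  family <- sub("J$", "", m)
  if (!family %in% c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    abort(sprintf("unknown model '%s' (expected one of %s)", model, paste(biogeo_models(), collapse = ", ")))
  }
  list(family = family, founder = founder, name = paste0(family, if (founder) "+J" else ""))
}

#' Cladogenetic event table
#'
#' Enumerates the ordered daughter-range pairs allowed at a speciation
#' node for each possible parent range, with their probabilities. Event
#' classes (P = parent range):
#'
#' * narrow sympatry (`|P| = 1`): both daughters inherit P — all families;
#' * subset sympatry (`|P| >= 2`, DEC family only): one daughter keeps P,
#'   the other is a single area within P, both orders;
#' * vicariance (`|P| >= 2`): P splits into two disjoint non-empty ranges
#'   covering P; DEC restricts one side to a single area, DIVALIKE allows
#'   any split, BAYAREALIKE forbids vicariance;
#' * identity copying (`|P| >= 2`, BAYAREALIKE only): both daughters keep P;
#' * founder event (any P, weight `j` per ordered event): one daughter
#'   keeps P, the other jumps to a single area outside P.
#'
#' Every non-founder event carries weight `(3 - j) / 3` and every founder
#' event weight `j`, normalized to probabilities within each parent range,
#' which ties the natural scale of `j` to `[0, 3]`.
#'
#' @param space A `range_state_space`.
#' @param model Model name (see [model_spec()]); a `+J` model with `j = 0`
#'   reduces to its base model.
#' @param j Founder-event weight in `[0, 3]`.
#' @return A tibble with integer state-index columns `parent`, `left`,
#'   `right`, the event `type`, `weight` and normalized `prob`.
#' @export
#' @examples
#' sp <- build_state_space(c("A", "B"))
#' clado_table(sp, "DEC") # parent AB: 2 vicariance + 4 subset sympatry
clado_table <- function(space, model, j = 0) {
  spec <- model_spec(model)
  if (j < 0 || j > 3) abort("j must lie in [0, 3]")
  if (j > 0 && !spec$founder) abort(sprintf("model %s has no founder parameter; j must be 0", spec$name))
  clado_weighted(clado_events(space, spec), j)
}

# event structure only (types and daughter pairs); weights depend on j and
# are filled in by clado_weighted(), so optimizers can reuse the structure
clado_events <- function(space, spec) {
  n <- length(space$areas)
  non_founder_w <- 1
  j <- 1
  rows <- vector("list", length(space$mask))
  for (i in seq_along(space$mask)) {
    mask <- space$mask[i]
    if (mask == 0L) next
    members <- mask_areas(mask, n)
    ev <- list()
    add <- function(lmask, rmask, type, w) {
      li <- space$index_of[lmask + 1L]; ri <- space$index_of[rmask + 1L]
      if (is.na(li) || is.na(ri)) return(invisible(NULL))
      ev[[length(ev) + 1L]] <<- c(li, ri, w, type)
    }
    if (length(members) == 1L) {
      add(mask, mask, 1L, non_founder_w) # narrow sympatry
    } else {
      if (spec$family == "DEC") {
        for (a in members) {
          bit <- bitwShiftL(1L, a - 1L)
          add(mask, bit, 2L, non_founder_w) # subset sympatry, both orders
          add(bit, mask, 2L, non_founder_w)
        }
      }
      if (spec$family %in% c("DEC", "DIVALIKE")) {
        # ordered splits: every nonempty proper submask L paired with P \ L
        sub <- bitwAnd(mask - 1L, mask)
        while (sub > 0L) {
          comp <- bitwAnd(bitwXor(mask, sub), mask)
          sizes <- c(
            sum(bitwAnd(bitwShiftR(sub, 0:(n - 1L)), 1L)),
            sum(bitwAnd(bitwShiftR(comp, 0:(n - 1L)), 1L))
          )
          ok <- spec$family == "DIVALIKE" || min(sizes) == 1L
          if (ok) add(sub, comp, 3L, non_founder_w) # vicariance
          sub <- bitwAnd(sub - 1L, mask)
        }
      }
      if (spec$family == "BAYAREALIKE") {
        add(mask, mask, 4L, non_founder_w) # identity copying
      }
    }
    if (spec$founder) {
      for (a in setdiff(seq_len(n), members)) {
        bit <- bitwShiftL(1L, a - 1L)
        add(mask, bit, 5L, j)
        add(bit, mask, 5L, j)
      }
    }
    if (length(ev)) {
      em <- do.call(rbind, ev)
      rows[[i]] <- cbind(parent = i, em)
    }
  }
  tab <- do.call(rbind, rows)
  tibble::tibble(
    parent = as.integer(tab[, 1]),
    left = as.integer(tab[, 2]),
    right = as.integer(tab[, 3]),
    type = c("sympatry", "subset_sympatry", "vicariance", "identity", "founder")[as.integer(tab[, 5])]
  )
}

# attach j-dependent weights and normalized probabilities to an event
# structure; zero-weight events (founder rows at j = 0, non-founder rows at
# exactly j = 3) are not allowed events and are dropped -- a parent left
# without any event cannot speciate and contributes a zero partial
clado_weighted <- function(events, j) {
  w <- ifelse(events$type == "founder", j, (3 - j) / 3)
  out <- events[w > 0, ]
  out$weight <- w[w > 0]
  tot <- tapply(out$weight, out$parent, sum)
  out$prob <- as.numeric(out$weight / tot[as.character(out$parent)])
  out[, c("parent", "left", "right", "weight", "type", "prob")]
}
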