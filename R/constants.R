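#' @name lobe_codes
#' @title Lobe label codes
#' @description Integer label codes used throughout the package:
#' 0 = background, 1 = right superior lobe (RUL), 2 = right middle lobe (RML),
#' 3 = right inferior lobe (RLL), 4 = left superior lobe (LUL),
#' 5 = left inferior lobe (LLL). The left lung anatomically has no middle
#' lobe, which is the root of the planar equal-thirds redistribution rule.
#' @export
lobe_codes <- c(RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLL = 5L)

#' @rdname lobe_codes
#' @export
lobe_names <- names(lobe_codes)

right_lobe_codes <- 1:3
left_lobe_codes <- 4:5
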