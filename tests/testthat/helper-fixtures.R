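# Shared fixtures. Heavy objects (the full-size phantom case and its
# registration chain) are built once per test run and memoized here.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# small anatomy phantom for unit tests (fast: ~1 s)
small_spec <- function(...) {
  defaults <- list(
    shape = c(16L, 48L, 48L),
    applicator = list(n_rods = 1L, radius_mm = 3, hu = 1500,
                      half_length_mm = 12, x_offsets_mm = 0),
    bumps = list(list(center = c(8, 26, 24),
                      amp = c(0.3, 1.5, 0.8), width = 10)),
    texture_bands = list(
      list(n = 20L, amp_hu = 120, sigma_mm = c(8, 14)),
      list(n = 40L, amp_hu = 80, sigma_mm = c(2.5, 5))),
    n_landmarks = 15L)
  over <- list(...)
  do.call(phantom_spec, c(over, defaults[setdiff(names(defaults), names(over))]))
}

small_case <- function() memo("small_case", function() make_case(small_spec()))

# constant-value volume helper
const_vol <- function(value, dim = c(4, 5, 6), spacing = c(1, 1, 1)) {
  image_volume(array(value, dim), spacing)
}

# volume linear in x: v = a * x_index
ramp_x <- function(a = 3, dim = c(8, 10, 12), spacing = c(1, 1, 1)) {
  image_volume(array(rep(a * (seq_len(dim[3]) - 1), each = dim[1] * dim[2]), dim),
               spacing)
}

full_mask <- function(vol) {
  structure_mask("all", array(TRUE, dim(vol$data)), vol$spacing, vol$origin)
}

# full-size case + registration chain used by the acceptance checks
full_chain <- function() memo("full_chain", function() {
  cs <- make_case(phantom_spec())
  b <- cs$bundle
  ref <- replace_applicator(b$reference_ct, b$masks$applicator_ref,
                            inpaint_params(seed = 2))
  body <- b$masks$body_ref
  t_aff <- affine_register(b$floating_ct, ref, affine_reg_params(), body)
  f_aff <- affine_to_field(t_aff, geometry_of(ref))
  field_direct <- pyramid_lk_register(ref, b$floating_ct, lk_params(2, 3))
  field_chain <- pyramid_lk_register(ref, b$floating_ct, lk_params(2, 3),
                                     init_field = f_aff)
  list(cs = cs, ref = ref, body = body, t_aff = t_aff, f_aff = f_aff,
       field_direct = field_direct, field_chain = field_chain)
})

mean_epe <- function(field, truth, mask) {
  e <- sqrt(apply((field$disp - truth$disp)^2, c(1, 2, 3), sum))
  mean(e[mask])
}
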