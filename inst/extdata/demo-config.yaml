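# Demo pipeline: recover the adhesion energy from synthetic buckles,
# tilt/order statistics of an undulated multilayer, and scattering fits.
seed: 42
verbosity: info
stages:
  buckles:
    n_buckles: 12
    gamma: 0.22
    e_mpa: 42
    thickness_range: [70, 150]
    strains: [0.05, 0.10, 0.14]
    rel_noise: 0.10
  multilayer:
    n_layers: 4
    lipids_per_layer: 2500
    # slope amplitude 2*pi*A/wavelength = tan(22.5 deg)
    amplitude: 26.3695
    wavelength: 400
    angular_noise_sd: 0
    bin_width: 1
    correlate_layers: [0, 1]
    segments: 50
  scattering:
    peaks:
      - {q0: 1.5141, fwhm: 0.061003, amplitude: 100}
    q_min: 1.2
    q_max: 1.8
    q_step: 0.0005
    background: [2, 0]
    noise_sd: 0
  topography:
    nx: 512
    ny: 128
    pixel_size: 10
    wrinkle_amplitude: 6.2225
    wrinkle_wavelength: 640
    noise_sd: 0
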