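# Simulated peak amplitudes (dB) of the vibroacoustic and hydroacoustic
# tinnitus sources before and after sigmoid-plate reconstruction with the
# three transtemporal repair techniques: temporalis fascia-auricular
# cartilage (TF-AC), solidified gelatin sponge (SGS), and solidified
# gelatin sponge-bone wax (SGS-BW).
- label: TF-AC
  pre_vibro_peak: 72.8
  pre_hydro_peak: 70.4
  post_vibro_peak: 68.6
  post_hydro_peak: 65.9
- label: SGS
  pre_vibro_peak: 72.8
  pre_hydro_peak: 70.4
  post_vibro_peak: 63.1
  post_hydro_peak: 61.5
- label: SGS-BW
  pre_vibro_peak: 72.8
  pre_hydro_peak: 70.4
  post_vibro_peak: 42.4
  post_hydro_peak: 39.2
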