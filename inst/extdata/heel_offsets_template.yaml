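# Tracker-to-heel offset template (PLACEHOLDER values -- synthetic).
# Each entry maps a shoe-size label to the heel position expressed in the
# tracker's local frame, in meters: [ox, oy, oz]. Measure these per shoe
# size with a static capture (e.g. a camera-based system) and replace the
# placeholders; the package never invents anthropometric constants.
EU40: [-0.14, 0.00, -0.07]
EU42: [-0.15, 0.00, -0.08]
EU44: [-0.16, 0.00, -0.08]
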