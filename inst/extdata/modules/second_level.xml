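<interface>
  <currenttask name="second_level" domain="study"
               desc="Across-subject one-sample t-test per first-level contrast" modality="MRI">
    <permanenceofoutput>4</permanenceofoutput>
    <inputstreams><stream>con</stream></inputstreams>
    <outputstreams><stream>group_stats</stream></outputstreams>
  </currenttask>
</interface>
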