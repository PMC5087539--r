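predicted,actual,count
building,building,158
building,non_building,57
non_building,building,29
non_building,non_building,330
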