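I never thought I would be writing a post like this, but last month I had a
stroke and I want to tell the whole story. It started out of nowhere on an
ordinary morning. My speech suddenly did not make sense and was slurred, and
I could not pick up my arm or my leg on one side of my body. Half of my face
felt numb and my smile looked crooked in the mirror. I felt confused and
dizzy, the room would not stop spinning, and a terrible headache came on out
of nowhere. I tried to stand and could not keep my balance. My vision went
blurry in one eye. My wife called 911 right away and the paramedics arrived
within minutes. They rushed me to the emergency room at the hospital, where
the doctors ran a scan and I was diagnosed with a stroke. The treatment
started quickly and I am slowly recovering. If you ever notice slurred
speech, weakness on one side, confusion, or a sudden headache like that,
do not wait. Call 911 immediately.
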