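ProteinName,PeptideSequence,PrecursorCharge,FragmentIon,ProductCharge,IsotopeLabelType,Condition,BioReplicate,Run,Intensity
sp|P1|ONE,pepA,2,NA,NA,L,A,1,runA,1000
sp|P1|ONE,pepA,2,NA,NA,L,B,1,runB,2000
sp|P2|TWO;sp|P3|THREE,pepB,2,NA,NA,L,A,1,runA,500
sp|P2|TWO;sp|P3|THREE,pepB,2,NA,NA,L,B,1,runB,480
sp|P4|FOUR,pepC,2,NA,NA,L,A,1,runA,250
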