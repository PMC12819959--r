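benchmark,method,arch_a,arch_b,mean_a,mean_b,dom_published
lvot,input_x_grad,R50,EB0,0.106,0.218,0.112
lvot,guided_backprop,R50,EB0,0.152,0.318,0.166
lvot,guided_grad_cam,R50,EB0,0.325,0.453,0.128
lvot,grad_cam,R50,EB0,0.547,0.569,0.022
lvot,normgrad_scaling,R50,EB0,0.497,0.778,0.281
lvot,normgrad_scaling_multi,R50,EB0,0.600,0.620,0.020
lvot,normgrad_conv1x1,R50,EB0,0.479,0.754,0.275
lvot,normgrad_conv1x1_multi,R50,EB0,0.611,0.634,0.023
lvot,normgrad_conv3x3,R50,EB0,0.430,0.728,0.298
lvot,normgrad_conv3x3_multi,R50,EB0,0.602,0.607,0.005
object_cxr,input_x_grad,R34,EB0,0.663,0.617,0.046
object_cxr,guided_backprop,R34,EB0,0.640,0.595,0.045
object_cxr,guided_grad_cam,R34,EB0,0.645,0.784,0.139
object_cxr,grad_cam,R34,EB0,0.545,0.771,0.226
object_cxr,normgrad_scaling,R34,EB0,0.852,0.857,0.005
object_cxr,normgrad_scaling_multi,R34,EB0,0.843,0.856,0.013
object_cxr,normgrad_conv1x1,R34,EB0,0.851,0.850,0.001
object_cxr,normgrad_conv1x1_multi,R34,EB0,0.839,0.851,0.011
object_cxr,normgrad_conv3x3,R34,EB0,0.853,0.863,0.009
object_cxr,normgrad_conv3x3_multi,R34,EB0,0.845,0.859,0.014
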